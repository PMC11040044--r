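date,tmean,tmin,tmax,rain,srad
2003-01-22,27.67,24.59,30.76,11.67,14.52
2003-01-23,28.09,24.72,31.45,11.15,17.84
2003-01-24,27.26,24.32,30.19,0,26.78
2003-01-25,29.35,26.62,32.08,11.72,16.04
2003-01-26,29.42,26.45,32.39,0.12,15.9
2003-01-27,28.21,24.58,31.84,52.34,17.17
2003-01-28,28.8,24.14,33.46,30.62,13.35
2003-01-29,29.49,25.66,33.31,0,27.97
2003-01-30,29.79,25.82,33.76,4.91,15.98
2003-01-31,29.03,27.02,31.05,0.82,17.1
2003-02-01,30.5,26.71,34.29,0,30.13
2003-02-02,30.3,27.12,33.47,0,26.7
2003-02-03,29.04,27.21,30.86,0.43,16.68
2003-02-04,26.4,22.99,29.82,0,28.96
2003-02-05,28.23,25.36,31.11,0,30.12
2003-02-06,28.23,24.05,32.4,2.62,15.96
2003-02-07,28.25,25.86,30.64,0,30
2003-02-08,29.32,26.67,31.98,0.51,16.21
2003-02-09,29.94,27.68,32.2,0,27.62
2003-02-10,30.12,27.26,32.98,0,28.88
2003-02-11,30.6,27.28,33.92,0,28.48
2003-02-12,30.78,28.37,33.2,0,28.6
2003-02-13,30.13,26.47,33.8,0,29.56
2003-02-14,27.41,25.37,29.44,3.44,15.49
2003-02-15,28.36,26.2,30.53,27.82,15.55
2003-02-16,28.29,24.14,32.44,7.02,15.58
2003-02-17,28.12,25.94,30.31,0,29.49
2003-02-18,26.56,23.23,29.89,0,30.84
2003-02-19,26.56,23.86,29.25,0,29.23
2003-02-20,27.53,24.21,30.86,7.58,17.44
2003-02-21,29.25,24.9,33.6,5.4,18.56
2003-02-22,28.84,24.57,33.11,0,26.65
2003-02-23,29.09,26.36,31.83,52.29,13.4
2003-02-24,28.78,27.61,29.95,0.27,13.94
2003-02-25,27.1,22.1,32.1,1.86,16.05
2003-02-26,26.98,23.45,30.52,50.15,15.66
2003-02-27,26.92,23.48,30.35,2.62,11.36
2003-02-28,27.24,24.25,30.23,0,29.07
2003-03-01,28.73,25.32,32.14,1.8,15.18
2003-03-02,29.4,26.53,32.27,0,27.01
2003-03-03,28.85,25.51,32.19,0,27.66
2003-03-04,28.36,25.68,31.04,0,24.95
2003-03-05,29.06,27.15,30.96,1.78,14.29
2003-03-06,29.39,25.6,33.18,0,28.42
2003-03-07,28.24,24.03,32.46,2.42,18.31
2003-03-08,27.42,24.67,30.17,0,27.75
2003-03-09,28.02,26.02,30.01,8.1,16.34
2003-03-10,28.87,25.36,32.39,9.37,12.58
2003-03-11,28.5,25.53,31.46,0,28.07
2003-03-12,29.33,27.71,30.94,21.44,16.78
2003-03-13,29.37,26.37,32.37,0,25.79
2003-03-14,28.28,25.78,30.78,2.62,15.28
2003-03-15,28.56,25.84,31.29,0,27.54
2003-03-16,27.14,25.06,29.21,12.27,18.11
2003-03-17,28.95,24.51,33.39,8.76,13.21
2003-03-18,30.82,28.08,33.55,0,27.44
2003-03-19,29.54,27.82,31.25,9.86,16.79
2003-03-20,27.89,24.73,31.05,11.78,16.05
2003-03-21,28.51,25.3,31.72,5.03,15.09
2003-03-22,28.16,25.95,30.37,10.21,14.38
2003-03-23,30.7,29.7,31.7,0,25.71
2003-03-24,29.78,27.3,32.27,3.47,15.76
2003-03-25,29.94,26.48,33.4,0.14,12.89
2003-03-26,29.32,26.36,32.27,6.25,12.64
2003-03-27,28.02,25.1,30.95,0,24.08
2003-03-28,28.14,24.69,31.59,7.9,12.25
2003-03-29,26.02,23.97,28.07,0,22.53
2003-03-30,28.13,24.25,32,17.09,16.13
2003-03-31,28.15,25.15,31.15,0,23.41
2003-04-01,30.38,26.82,33.95,6.84,13.35
2003-04-02,30.07,26.24,33.9,0,22.92
2003-04-03,28.54,25.36,31.72,0,25.12
2003-04-04,28.92,26.62,31.22,0,25.04
2003-04-05,27.48,23.54,31.41,0,25.85
2003-04-06,26.11,24.71,27.51,0,23.47
2003-04-07,26.84,24.28,29.41,0,25.7
2003-04-08,26.54,23.74,29.34,1.36,13.84
2003-04-09,26.81,23.94,29.68,0,22.03
2003-04-10,27.07,23.26,30.89,1.62,15.1
2003-04-11,26.52,23.41,29.63,0,25.63
2003-04-12,26.15,22.82,29.47,8.93,14.49
2003-04-13,26.36,23.41,29.3,0,22.8
2003-04-14,27.94,25.14,30.74,0,21.48
2003-04-15,26.07,22.51,29.63,0,23.22
2003-04-16,27.08,23.17,31,0,21.29
2003-04-17,27.5,26.42,28.57,6.79,10.74
2003-04-18,28.58,25.12,32.04,3.17,13.98
2003-04-19,27.83,24.53,31.13,5.81,12.61
2003-04-20,28.04,25.38,30.7,0,22.12
2003-04-21,28.06,24.3,31.82,25.83,12.05
2003-04-22,27.18,24.49,29.87,0,24.12
2003-04-23,28.48,25.71,31.25,0.18,10.74
2003-04-24,29.33,25.65,33.02,0,21.66
2003-04-25,29.41,25.04,33.79,0,22.84
2003-04-26,30.44,27.22,33.66,0,22.38
2003-04-27,30.02,27.36,32.68,5.51,11.75
2003-04-28,27.7,25.65,29.74,0,21.74
2003-04-29,26.84,24.1,29.57,1.71,12.17
2003-04-30,25.51,23.26,27.76,0.84,14.43
2003-05-01,25.4,22.61,28.19,0,21.64
2003-05-02,25.16,21.84,28.47,0,20.62
2003-05-03,25.7,23.39,28.02,0,22.77
2003-05-04,25.03,19.91,30.15,5,10.59
2003-05-05,25.73,22.61,28.86,0,21.78
2003-05-06,25.32,21.41,29.22,0,22.52
2003-05-07,27.68,26.52,28.85,0,19.55
2003-05-08,28.18,24.59,31.77,0,21.24
2003-05-09,28.73,26.78,30.68,0,21.89
2003-05-10,28.53,24.79,32.26,0,21.99
2003-05-11,29.81,26.49,33.13,0,22.38
2003-05-12,28.15,25.47,30.82,12.37,13.96
2003-05-13,27.17,23.11,31.23,0,20.65
2003-05-14,28.56,26.12,31,0,19.34
2003-05-15,27.23,24.7,29.77,0,19.37
2003-05-16,26.78,24.58,28.98,0,20.97
2003-05-17,26.26,23.79,28.72,0,18.28
2003-05-18,25.96,22.21,29.72,0,20.58
2003-05-19,25.8,22.45,29.14,0,18.62
2003-05-20,26.52,22.72,30.32,3.77,10.3
2003-05-21,26.28,23.59,28.97,0,20.17
2003-05-22,25.75,22.45,29.05,5.62,10.6
2003-05-23,27.4,24.2,30.59,0,18.72
2003-05-24,26.83,24.97,28.69,0,18.84
2003-05-25,26.47,22.05,30.89,0,21.1
2003-05-26,26.3,23.19,29.4,0,17.93
2003-05-27,27.06,23.45,30.67,4.96,11.2
2003-05-28,26.72,22.96,30.49,0,18.82
2003-05-29,26.52,23.56,29.48,0,21.48
2003-05-30,25.66,22.91,28.42,0,19.05
2003-05-31,25.45,21.74,29.17,0,21.16
2003-06-01,25.72,23.56,27.88,0,20.06
2003-06-02,25.18,20.61,29.76,21.27,9.19
2003-06-03,26.04,23.34,28.73,0,19.59
2003-06-04,24.37,20.05,28.69,0,19.74
2003-06-05,25.21,21,29.42,9.23,10.85
2003-06-06,23.76,20.69,26.82,2.18,8.69
2003-06-07,24.1,20.64,27.55,0,21.02
2003-06-08,24.08,21.9,26.26,0,18.63
2003-06-09,23.92,20.66,27.18,0,17.29
2003-06-10,24.46,20.63,28.3,0,20.1
2003-06-11,22.79,19.71,25.87,0,18.47
2003-06-12,25.01,22.38,27.65,0,18.98
2003-06-13,23.44,20.96,25.91,0,17.86
2003-06-14,23.65,20.68,26.62,0,16.76
2003-06-15,23.08,19.22,26.93,0,18.47
2003-06-16,23.07,20.46,25.69,0,19.43
2003-06-17,26.19,23.28,29.09,0,18.6
2003-06-18,26.08,24.12,28.05,0,18.64
2003-06-19,24.57,21.18,27.97,0,18.84
2003-06-20,23.12,19.07,27.17,20.22,11.05
2003-06-21,24.4,20.2,28.59,0,18.31
2003-06-22,24.77,21.12,28.42,0,18.27
2003-06-23,24.7,23.19,26.2,0,17.81
2003-06-24,23.97,20.59,27.36,0,17.13
2003-06-25,22.84,19.48,26.21,0,17.07
2003-06-26,22.5,19.78,25.22,0,17.77
2003-06-27,24.54,21.41,27.68,3.66,9.85
2003-06-28,24.18,21.87,26.49,0,18.22
2003-06-29,23.09,19.54,26.63,15.25,9.36
2003-06-30,25.9,23.16,28.63,0,17.72
2003-07-01,26.27,24.52,28.01,0,20.29
2003-07-02,25.8,23.09,28.5,0,19.11
2003-07-03,26.89,22.8,30.98,0,19.02
2003-07-04,27.46,24.73,30.19,0,18.74
2003-07-05,26.2,22.61,29.79,0,17.81
2003-07-06,28.42,24.67,32.18,0,18.19
2003-07-07,27.27,24.27,30.27,0,18.46
2003-07-08,25.17,22.45,27.89,0,18.99
2003-07-09,25.11,22.53,27.69,4.42,10.78
2003-07-10,25.45,21.86,29.04,0,20.93
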