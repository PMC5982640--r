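measure,subject,trial,ratio
synchronicity,1,1,0.93
synchronicity,1,2,1.06
synchronicity,1,3,0.86
synchronicity,1,4,0.73
synchronicity,1,5,1.54
synchronicity,1,6,0.93
synchronicity,1,7,0.74
synchronicity,1,8,1.01
synchronicity,2,1,0.79
synchronicity,2,2,1.16
synchronicity,2,3,0.91
synchronicity,2,4,0.61
synchronicity,2,5,0.74
synchronicity,2,6,0.93
synchronicity,2,7,0.72
synchronicity,2,8,0.84
synchronicity,3,1,0.95
synchronicity,3,2,0.74
synchronicity,3,3,1.21
synchronicity,3,4,0.64
synchronicity,3,5,0.73
synchronicity,3,6,0.71
synchronicity,3,7,2.14
synchronicity,3,8,0.87
symmetry,1,1,1.09
symmetry,1,2,1.29
symmetry,1,3,0.82
symmetry,1,4,0.85
symmetry,1,5,1.54
symmetry,1,6,1.01
symmetry,1,7,0.78
symmetry,1,8,1.16
symmetry,2,1,0.79
symmetry,2,2,1
symmetry,2,3,0.93
symmetry,2,4,0.6
symmetry,2,5,0.78
symmetry,2,6,0.83
symmetry,2,7,0.68
symmetry,2,8,0.76
symmetry,3,1,0.95
symmetry,3,2,0.94
symmetry,3,3,0.71
symmetry,3,4,0.87
symmetry,3,5,0.82
symmetry,3,6,0.76
symmetry,3,7,3.4
symmetry,3,8,1
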