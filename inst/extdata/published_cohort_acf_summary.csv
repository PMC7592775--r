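parameter,cvp_n,cvp_mean,cvp_sd,cvp_min,cvp_max,csa_n,csa_mean,csa_sd,csa_min,csa_max
signal_mean,34,5.998,2.874,1.066,10.896,34,0.984,0.497,0.193,1.908
signal_sd,34,1.21,0.462,0.554,2.173,34,0.05,0.03,0.008,0.114
signal_median,34,6.002,2.893,0.758,10.819,34,0.979,0.497,0.185,1.897
signal_min,34,3.422,3.355,-2.271,9.664,34,0.879,0.466,0.125,1.813
signal_max,34,8.667,2.660,3.34,12.739,34,1.090,0.525,0.287,2.040
lag0,34,1.000,0.000,1.000,1.000,34,1.000,0.000,1.000,1.000
lag20,34,0.127,0.339,-0.428,0.664,34,0.384,0.314,-0.429,0.841
lag40,34,-0.19,0.214,-0.549,0.264,34,-0.163,0.344,-0.830,0.542
lag60,34,-0.173,0.270,-0.636,0.587,34,-0.321,0.307,-0.784,0.602
lag80,34,-0.206,0.284,-0.64,0.731,34,-0.290,0.283,-0.656,0.642
lag100,34,-0.046,0.361,-0.572,0.727,34,-0.051,0.414,-0.643,0.682
lag120,34,0.046,0.354,-0.459,0.655,34,0.033,0.459,-0.723,0.767
lag140,34,0.061,0.263,-0.425,0.675,34,-0.039,0.397,-0.709,0.742
lag160,34,-0.036,0.304,-0.45,0.675,34,-0.097,0.332,-0.590,0.663
lag180,34,-0.085,0.250,-0.585,0.363,34,-0.114,0.314,-0.557,0.549
lag200,34,-0.012,0.265,-0.466,0.562,34,-0.034,0.316,-0.547,0.616
lag220,34,-0.041,0.254,-0.473,0.534,34,0.031,0.299,-0.583,0.632
lag240,34,0.054,0.250,-0.501,0.544,34,0.102,0.322,-0.459,0.674
lag260,34,0.078,0.279,-0.372,0.734,34,0.101,0.319,-0.370,0.835
lag280,34,-0.024,0.226,-0.349,0.552,34,0.050,0.287,-0.449,0.717
lag300,34,-0.018,0.197,-0.360,0.411,34,0.017,0.263,-0.425,0.574
lag320,34,0.027,0.237,-0.379,0.54,34,0.007,0.266,-0.420,0.566
lag340,34,0.044,0.193,-0.312,0.447,34,0.000,0.246,-0.387,0.597
lag360,34,-0.015,0.152,-0.429,0.304,34,-0.018,0.219,-0.494,0.483
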