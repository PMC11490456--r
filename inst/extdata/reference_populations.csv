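population,sex,code,n_greek,greek_mm,n_ref,ref_mm,sig
cretan,M,Sg,50,6.54,32,5.7,0.00**
cretan,M,G,49,6.28,32,5.9,0.06
cretan,M,N,50,8.02,32,7.8,0.35
cretan,M,Mn,41,3.30,30,4.5,0.00**
cretan,M,Rhi,42,3.30,30,3.8,0.00**
cretan,M,Fe,45,6.27,32,6.1,0.42
cretan,M,So,49,9.75,32,8.6,0.00**
cretan,M,Sk,47,10.04,32,10.4,0.14
cretan,M,Or,50,7.41,30,9.1,0.00**
cretan,M,Smc,39,29.12,20,29.9,0.19
cretan,M,Ft,48,6.19,32,6.4,0.32
cretan,M,Fmt,48,7.91,32,7.0,0.00**
cretan,M,Ec,45,10.61,32,9.4,0.03*
cretan,M,Mz,41,9.49,24,11.2,0.00**
cretan,M,Zm,36,15.75,20,16.6,0.28
cretan,M,Ju,48,9.66,32,9.6,0.84
cretan,M,Zy,49,9.11,32,9.7,0.09
cretan,M,Al,39,9.75,21,10.9,0.00**
cretan,M,Mnm,45,3.24,30,2.9,0.00**
cretan,M,Nm,44,6.04,29,4.0,0.00**
cretan,M,Fmo,49,11.09,32,10.2,0.10
cretan,F,Sg,48,5.93,32,4.8,0.00**
cretan,F,G,49,6.03,32,5.5,0.00**
cretan,F,N,50,6.76,32,6.7,0.76
cretan,F,Mn,44,2.57,29,3.0,0.00**
cretan,F,Rhi,44,2.62,24,2.6,0.70
cretan,F,Fe,49,5.55,32,3.9,0.00**
cretan,F,So,50,8.40,32,7.2,0.00**
cretan,F,Sk,49,8.52,32,9.3,0.00**
cretan,F,Or,49,6.52,24,7.4,0.00**
cretan,F,Smc,36,28.54,10,27.3,0.01**
cretan,F,Ft,50,5.77,32,4.6,0.00**
cretan,F,Fmt,50,7.61,32,6.0,0.00**
cretan,F,Ec,50,9.56,29,7.7,0.00**
cretan,F,Mz,46,10.39,19,11.4,0.00**
cretan,F,Zm,44,15.38,13,14.8,0.14
cretan,F,Ju,50,10.62,31,9.9,0.00**
cretan,F,Zy,50,9.89,31,9.0,0.01**
cretan,F,Al,42,9.23,10,10.0,0.02*
cretan,F,Mnm,50,3.00,27,2.1,0.00**
cretan,F,Nm,33,4.20,20,2.8,0.00**
cretan,F,Fmo,50,10.04,32,10.1,0.91
turkish,M,Sg,50,6.54,42,4.21,0.00**
turkish,M,G,49,6.28,42,6.40,0.53
turkish,M,N,50,8.02,42,7.32,0.00**
turkish,M,Rhi,42,3.30,42,2.97,0.00**
turkish,M,Fe,45,6.27,42,4.48,0.00**
turkish,M,So,49,9.75,42,6.94,0.00**
turkish,M,Or,50,7.41,42,5.92,0.00**
turkish,M,Mz,41,9.49,42,7.90,0.00**
turkish,M,Zy,49,9.11,42,7.83,0.00**
turkish,F,Sg,48,5.93,42,3.94,0.00**
turkish,F,G,49,6.03,42,6.03,0.99
turkish,F,N,50,6.76,42,7.16,0.03*
turkish,F,Rhi,44,2.62,42,2.38,0.00**
turkish,F,Fe,49,5.55,42,4.02,0.00**
turkish,F,So,50,8.40,42,6.17,0.00**
turkish,F,Or,49,6.52,42,5.47,0.00**
turkish,F,Mz,46,10.39,42,9.40,0.00**
turkish,F,Zy,50,9.89,42,8.06,0.00**
korean,M,Sg,50,6.54,50,5.3,0.00**
korean,M,G,49,6.28,50,5.6,0.00**
korean,M,N,50,8.02,50,6.4,0.00**
korean,M,Rhi,42,3.30,50,2.3,0.00**
korean,M,Fe,45,6.27,50,6.2,0.70
korean,M,So,49,9.75,50,7.2,0.00**
korean,M,Mz,41,9.49,50,8.6,0.00**
korean,M,Zy,49,9.11,50,8.1,0.00**
korean,F,Sg,48,5.93,50,4.8,0.00**
korean,F,G,49,6.03,50,5.3,0.00**
korean,F,N,50,6.76,50,5.4,0.00**
korean,F,Rhi,44,2.62,50,2.2,0.00**
korean,F,Fe,49,5.55,50,5.4,0.39
korean,F,So,50,8.40,50,6.4,0.00**
korean,F,Mz,46,10.39,50,10.2,0.41
korean,F,Zy,50,9.89,50,8.7,0.00**
czech,M,G,49,6.28,56,6.29,0.94
czech,M,N,50,8.02,56,9.41,0.00**
czech,M,Rhi,42,3.30,56,3.11,0.10
czech,M,OrL,50,7.18,56,8.37,0.00**
czech,M,OrR,50,7.41,56,8.35,0.01**
czech,M,EcL,49,10.67,56,5.85,0.00**
czech,M,EcR,45,10.61,56,5.84,0.00**
czech,M,ZyL,49,8.71,56,8.77,0.85
czech,M,ZyR,49,9.11,56,8.49,0.08
czech,M,JuL,49,9.42,56,9.72,0.30
czech,M,JuR,48,9.65,56,10.36,0.00**
czech,M,AlL,42,9.95,56,12.35,0.00**
czech,M,AlR,39,9.75,56,12.02,0.00**
czech,F,G,49,6.03,46,6.01,0.80
czech,F,N,50,6.76,46,8.25,0.00**
czech,F,Rhi,44,2.62,46,2.61,0.81
czech,F,OrL,47,6.34,46,7.47,0.00**
czech,F,OrR,49,6.52,46,7.22,0.01**
czech,F,EcL,48,9.66,46,5.85,0.00**
czech,F,EcR,50,9.56,46,5.87,0.00**
czech,F,ZyL,49,9.79,46,9.19,0.09
czech,F,ZyR,50,9.89,46,9.17,0.05*
czech,F,JuL,49,10.43,46,10.27,0.56
czech,F,JuR,50,10.62,46,10.56,0.82
czech,F,AlL,43,9.55,46,10.69,0.00**
czech,F,AlR,42,9.23,46,10.62,0.00**
french,pooled,G,98,6.16,366,6.5,0.00**
french,pooled,N,100,7.39,469,8.2,0.00**
french,pooled,Mn,85,2.92,321,5.5,0.00**
french,pooled,Rhi,86,2.96,459,3.0,0.54
french,pooled,Sk,96,9.26,373,9.7,0.03*
french,pooled,Or,99,6.97,371,8.6,0.00**
french,pooled,Smc,75,28.84,330,28.2,0.08
french,pooled,Ft,98,5.98,361,6.7,0.00**
french,pooled,Fmt,98,7.76,242,9.1,0.00**
french,pooled,Ec,95,10.06,372,7.8,0.00**
french,pooled,Zm,80,15.55,353,15.1,0.09
french,pooled,Ju,98,10.15,245,10.9,0.00**
french,pooled,Zy,99,9.50,364,10.0,0.04*
french,pooled,Co,99,17.73,215,16.7,0.02*
french,pooled,Mnm,95,3.11,328,3.5,0.00**
french,pooled,Nm,77,5.25,457,4.9,0.04*
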