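arm_id,drug_class,n,rmst6_pfs,rmst6_pfs_lo,rmst6_pfs_hi,rmst6_os,rmst6_os_lo,rmst6_os_hi,rmst12_pfs,rmst12_pfs_lo,rmst12_pfs_hi,rmst12_os,rmst12_os_lo,rmst12_os_hi
atezolizumab-bevacizumab,ICI,336,4.67,4.46,4.86,5.62,5.50,5.73,7.11,6.65,7.58,9.95,9.60,10.31
nivolumab,ICI,371,3.85,3.35,4.04,5.42,5.28,5.56,5.47,5.03,5.9,9.50,9.12,9.87
pembrolizumab-K240,ICI,278,3.65,3.40,3.89,5.37,5.22,5.52,5.19,4.68,5.70,9.23,8.79,9.66
pembrolizumab-K224,ICI,104,4.23,3.87,4.59,5.44,5.19,5.69,6.21,5.41,7.02,9.38,8.70,10.05
camrelizumab,ICI,217,3.32,3.07,3.57,5.35,5.16,5.23,4.51,3.99,5.04,9.29,8.79,9.79
nivolumab-ipilimumab-cabozantinib,ICI,35,4.72,4.13,5.32,5.37,4.84,5.89,7.17,5.77,8.57,9.76,8.38,11.41
nivolumab-cabozantinib,ICI,36,4.44,3.84,5.03,5.62,5.31,5.93,6.6,5.2,8,10.13,9.02,11.24
sorafenib-SUN1170,MKI,,3.52,3.35,3.69,4.81,4.56,5.07,4.61,4.28,7.93,7.08,6.44,7.71
sunitinib-SUN1170,MKI,,3.68,3.53,3.84,5.00,4.87,5.13,4.54,4.26,4.82,7.76,7.42,8.09
sorafenib-SARAH,MKI,,3.91,3.65,4.18,5.21,5.01,5.4,5.22,4.71,5.72,8.54,8.02,9.06
sorafenib-SIRVENIB,MKI,,4.48,4.25,4.72,5.28,5.06,5.49,6.16,5.59,6.72,8.63,8.05,9.21
sorafenib-CALGB80802,MKI,,3.68,3.39,3.97,5.00,4.70,5.24,4.75,4.20,5.30,8.03,7.44,8.63
sorafenib-SILIUS,MKI,,3.71,3.35,4.07,5.5,5.39,5.59,4.68,4.00,5.36,9.25,8.93,9.56
vandetanib-Hsu2012,MKI,,2.19,1.4,2.97,4.86,4.17,5.56,NA,NA,NA,NA,NA,NA
sorafenib-doxorubicin-AbouAlfa2010,MKI,,4.38,3.79,4.98,5.15,4.66,5.63,6.05,4.85,7.25,8.8,7.6,10.00
sorafenib-REFLECT,MKI,,3.96,3.77,4.14,5.43,5.32,5.54,5.43,5.05,5.81,9.04,8.71,9.36
lenvatinib-REFLECT,MKI,,4.85,4.67,5.00,5.54,5.43,5.64,7.78,7.38,8.16,9.29,9.6,9.91
sorafenib-IMbrave150,MKI,165,3.96,3.64,4.28,5.25,5.13,5.37,5.28,4.65,5.91,8.56,8.23,8.89
sorafenib-CheckMate459,MKI,372,4.02,3.83,4.21,5.40,5.27,5.54,5.35,4.96,5.74,9.25,8.87,9.63
cediranib-Zhu2013,MKI,,4.29,3.39,5.19,5.15,4.30,6.00,5.92,4.12,7.72,8.50,6.51,10.50
regorafenib-RESORCE,MKI,,3.71,3.51,3.91,5.22,5.08,5.36,4.89,4.49,5.29,8.63,8.23,9.03
cabozantinib-CELESTIAL,MKI,,4.19,4.01,4.36,5.30,5.16,5.44,5.29,5.66,6.03,8.76,8.39,9.12
ramucirumab-REACH,MKI,,3.31,2.00,3.61,5.17,4.97,5.37,4.39,3.84,4.94,8.18,7.64,8.72
ramucirumab-REACH2,MKI,,3.54,3.30,3.79,5.26,5.09,5.42,4.82,4.35,5.29,8.55,8.09,9.01
tivantinib-METIVHCC,MKI,,3.08,2.62,3.15,4.99,4.79,5.19,3.62,3.25,3.99,7.86,7.34,8.38
adipeg20-ADIPEG20,MKI,,3.19,3.01,3.37,4.47,4.29,4.65,3.69,3.40,3.98,6.75,6.34,7.16
axitinib-Kang2015,MKI,,3.75,3.41,4.09,5.37,4.84,5.89,4.98,4.32,5.62,9.19,8.56,9.82
tasquinimod-Escudier2017,MKI,,3.73,3.20,4.27,5.30,4.88,5.72,4.65,3.69,5.61,7.89,6.89,8.89
codrituzumab-AbouAlfa2016,MKI,,3.02,2.68,3.36,4.97,4.68,5.26,3.52,2.97,4.07,7.62,6.96,8.29
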