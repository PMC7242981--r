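# vocospan word inventory; phonemes: ascii transcription
"orthography","initial","vowel","final","neighborhood_density","log_frequency"
"soow","s","uw","w",15,2.54
"poom","p","uw","m",15,2.53
"hooz","h","uw","z",15,2.5
"fooz","f","uw","z",15,2.51
"sees","s","iy","s",15,2.51
"fom","f","aa","m",15,2.52
"peew","p","iy","w",11,1.85
"cheev","ch","iy","v",14,2.39
"ches","ch","eh","s",14,2.41
"chep","ch","eh","p",14,2.52
"shoaf","sh","ow","f",11,2.21
"shoz","sh","aa","z",19,3.14
"shayd","sh","ey","d",19,2
"woad","w","ow","d",17,2.59
"moop","m","uw","p",13,1.47
"meed","m","iy","d",17,2.5
"hoad","h","ow","d",14,2.68
"fov","f","aa","v",14,2.12
"sev","s","eh","v",18,2.75
"deech","d","iy","ch",12,2.62
"vep","v","eh","p",14,2.84
"hayv","h","ey","v",13,2.2
"wad","w","ae","d",15,2.16
"hes","h","eh","s",12,1.88
"doaf","d","ow","f",13,2.39
"mayw","m","ey","w",17,2.03
"fam","f","ae","m",16,2.74
"ped","p","eh","d",13,2.52
"choash","ch","ow","sh",16,3.27
"voz","v","aa","z",10,2.09
"peech","p","iy","ch",15,2.46
"waf","w","ae","f",15,2.47
"mays","m","ey","s",15,2.5
"how","h","aa","w",15,2.49
"mev","m","eh","v",15,2.49
"shayp","sh","ey","p",15,2.48
"veef","v","iy","f",19,3.15
"saych","s","ey","ch",16,2.61
"hov","h","aa","v",16,2.59
"waz","w","ae","z",16,2.48
"fop","f","aa","p",19,2.79
"choas","ch","ow","s",11,1.86
"shoosh","sh","uw","sh",11,3
"dooch","d","uw","ch",13,2.41
"chays","ch","ey","s",17,3.53
"veez","v","iy","z",13,2.5
"vap","v","ae","p",16,2.32
"paym","p","ey","m",16,2.88
"dosh","d","aa","sh",12,2.25
"shaym","sh","ey","m",18,2.38
"wof","w","aa","f",16,2.16
"vesh","v","eh","sh",17,2.8
"saw","s","ae","w",15,2.84
"wesh","w","eh","sh",18,3.12
"faf","f","ae","f",17,2.61
"doosh","d","uw","sh",13,2.97
"dam","d","ae","m",14,2.26
"mach","m","ae","ch",17,2.48
"poaw","p","ow","w",14,1.73
"soach","s","ow","ch",20,2.91
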