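species,element,mean_mg_per_kg,sd_mg_per_kg,detected,n_replicates
Morchella importuna,Cd,1.633,1.53,TRUE,3
Morchella importuna,Pb,3.058,2.71,TRUE,3
Morchella importuna,As,2.970,1.87,TRUE,3
Morchella importuna,Hg,0.021,0.01,TRUE,3
Tricholoma scalpturatum,Cd,0.928,0.72,TRUE,3
Tricholoma scalpturatum,Pb,1.028,0.87,TRUE,3
Tricholoma scalpturatum,As,0.939,0.32,TRUE,3
Tricholoma scalpturatum,Hg,0.033,0.02,TRUE,3
Infundibulicybe geotropa,Cd,3.501,2.15,TRUE,3
Infundibulicybe geotropa,Pb,1.536,0.93,TRUE,3
Infundibulicybe geotropa,As,1.840,1.21,TRUE,3
Infundibulicybe geotropa,Hg,0.519,0.32,TRUE,3
Tricholoma populinum,Cd,2.404,1.21,TRUE,3
Tricholoma populinum,Pb,1.467,0.77,TRUE,3
Tricholoma populinum,As,2.821,1.14,TRUE,3
Tricholoma populinum,Hg,0.022,0.01,TRUE,3
Pholiota carbonaria,Cd,2.968,1.34,TRUE,3
Pholiota carbonaria,Pb,2.187,1.11,TRUE,3
Pholiota carbonaria,As,1.952,1.32,TRUE,3
Pholiota carbonaria,Hg,0.089,0.07,TRUE,3
Laccaria laccata,Cd,10.059,3.24,TRUE,3
Laccaria laccata,Pb,2.182,1.16,TRUE,3
Laccaria laccata,As,2.000,1.43,TRUE,3
Laccaria laccata,Hg,ND,ND,FALSE,3
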