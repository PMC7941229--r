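id	S1	S2	S3
ACA[C>A]	0.0195722835304293	0.00260416666666667	0.00260416666666667
ACC[C>A]	0.0280763270103548	0.00260416666666667	0.00260416666666667
ACG[C>A]	0.0385256703491379	0.00260416666666667	0.00260416666666667
ACT[C>A]	0.0501924272558274	0.00260416666666667	0.00260416666666667
CCA[C>A]	0.06182871386349	0.00260416666666667	0.00260416666666667
CCC[C>A]	0.0718446772605093	0.00260416666666667	0.00260416666666667
CCG[C>A]	0.0786499905592106	0.00260416666666667	0.00260416666666667
CCT[C>A]	0.0810639441356366	0.00260416666666667	0.00260416666666667
GCA[C>A]	0.0786499905592106	0.00260416666666667	0.00260416666666667
GCC[C>A]	0.0718446772605093	0.00260416666666667	0.00260416666666667
GCG[C>A]	0.06182871386349	0.00260416666666667	0.00260416666666667
GCT[C>A]	0.0501924272558274	0.00260416666666667	0.00260416666666667
TCA[C>A]	0.0385256703491379	0.00260416666666667	0.00260416666666667
TCC[C>A]	0.0280763270103548	0.00260416666666667	0.00260416666666667
TCG[C>A]	0.0195722835304293	0.00260416666666667	0.00260416666666667
TCT[C>A]	0.0132225428731113	0.00260416666666667	0.00260416666666667
ACA[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
ACC[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
ACG[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
ACT[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
CCA[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
CCC[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
CCG[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
CCT[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
GCA[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
GCC[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
GCG[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
GCT[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
TCA[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
TCC[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
TCG[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
TCT[C>G]	0.00260416666666667	0.00260416666666667	0.00260416666666667
ACA[C>T]	0.00260416666666667	0.0195722835304293	0.00260416666666667
ACC[C>T]	0.00260416666666667	0.0280763270103548	0.00260416666666667
ACG[C>T]	0.00260416666666667	0.0385256703491379	0.00260416666666667
ACT[C>T]	0.00260416666666667	0.0501924272558274	0.00260416666666667
CCA[C>T]	0.00260416666666667	0.06182871386349	0.00260416666666667
CCC[C>T]	0.00260416666666667	0.0718446772605093	0.00260416666666667
CCG[C>T]	0.00260416666666667	0.0786499905592106	0.00260416666666667
CCT[C>T]	0.00260416666666667	0.0810639441356366	0.00260416666666667
GCA[C>T]	0.00260416666666667	0.0786499905592106	0.00260416666666667
GCC[C>T]	0.00260416666666667	0.0718446772605093	0.00260416666666667
GCG[C>T]	0.00260416666666667	0.06182871386349	0.00260416666666667
GCT[C>T]	0.00260416666666667	0.0501924272558274	0.00260416666666667
TCA[C>T]	0.00260416666666667	0.0385256703491379	0.00260416666666667
TCC[C>T]	0.00260416666666667	0.0280763270103548	0.00260416666666667
TCG[C>T]	0.00260416666666667	0.0195722835304293	0.00260416666666667
TCT[C>T]	0.00260416666666667	0.0132225428731113	0.00260416666666667
ATA[T>A]	0.00260416666666667	0.00260416666666667	0.00260417161524769
ATC[T>A]	0.00260416666666667	0.00260416666666667	0.00260418685996679
ATG[T>A]	0.00260416666666667	0.00260416666666667	0.00260424407549788
ATT[T>A]	0.00260416666666667	0.00260416666666667	0.00260444542657633
CTA[T>A]	0.00260416666666667	0.00260416666666667	0.00260510969928548
CTC[T>A]	0.00260416666666667	0.00260416666666667	0.00260716361813123
CTG[T>A]	0.00260416666666667	0.00260416666666667	0.00261311391103908
CTT[T>A]	0.00260416666666667	0.00260416666666667	0.00262925983405631
GTA[T>A]	0.00260416666666667	0.00260416666666667	0.00267027835726529
GTC[T>A]	0.00260416666666667	0.00260416666666667	0.0027677946723707
GTG[T>A]	0.00260416666666667	0.00260416666666667	0.00298461317830077
GTT[T>A]	0.00260416666666667	0.00260416666666667	0.00343513824584985
TTA[T>A]	0.00260416666666667	0.00260416666666667	0.00430920963970548
TTC[T>A]	0.00260416666666667	0.00260416666666667	0.00589072301690264
TTG[T>A]	0.00260416666666667	0.00260416666666667	0.00855535139978248
TTT[T>A]	0.00260416666666667	0.00260416666666667	0.012727472911582
ATA[T>C]	0.00260416666666667	0.00260416666666667	0.0187811639844983
ATC[T>C]	0.00260416666666667	0.00260416666666667	0.026888715910857
ATG[T>C]	0.00260416666666667	0.00260416666666667	0.0368508702572594
ATT[T>C]	0.00260416666666667	0.00260416666666667	0.047973677620189
CTA[T>C]	0.00260416666666667	0.00260416666666667	0.0590674353278393
CTC[T>C]	0.00260416666666667	0.00260416666666667	0.0686164155894681
CTG[T>C]	0.00260416666666667	0.00260416666666667	0.0751044387368808
CTT[T>C]	0.00260416666666667	0.00260416666666667	0.0774058444170014
GTA[T>C]	0.00260416666666667	0.00260416666666667	0.0751044387368808
GTC[T>C]	0.00260416666666667	0.00260416666666667	0.0686164155894681
GTG[T>C]	0.00260416666666667	0.00260416666666667	0.0590674353278393
GTT[T>C]	0.00260416666666667	0.00260416666666667	0.047973677620189
TTA[T>C]	0.00260416666666667	0.00260416666666667	0.0368508702572594
TTC[T>C]	0.00260416666666667	0.00260416666666667	0.026888715910857
TTG[T>C]	0.00260416666666667	0.00260416666666667	0.0187811639844983
TTT[T>C]	0.00260416666666667	0.00260416666666667	0.012727472911582
ATA[T>G]	0.00260416666666667	0.00260416666666667	0.00855535139978248
ATC[T>G]	0.00260416666666667	0.00260416666666667	0.00589072301690264
ATG[T>G]	0.00260416666666667	0.00260416666666667	0.00430920963970548
ATT[T>G]	0.00260416666666667	0.00260416666666667	0.00343513824584985
CTA[T>G]	0.00260416666666667	0.00260416666666667	0.00298461317830077
CTC[T>G]	0.00260416666666667	0.00260416666666667	0.0027677946723707
CTG[T>G]	0.00260416666666667	0.00260416666666667	0.00267027835726529
CTT[T>G]	0.00260416666666667	0.00260416666666667	0.00262925983405631
GTA[T>G]	0.00260416666666667	0.00260416666666667	0.00261311391103908
GTC[T>G]	0.00260416666666667	0.00260416666666667	0.00260716361813123
GTG[T>G]	0.00260416666666667	0.00260416666666667	0.00260510969928548
GTT[T>G]	0.00260416666666667	0.00260416666666667	0.00260444542657633
TTA[T>G]	0.00260416666666667	0.00260416666666667	0.00260424407549788
TTC[T>G]	0.00260416666666667	0.00260416666666667	0.00260418685996679
TTG[T>G]	0.00260416666666667	0.00260416666666667	0.00260417161524769
TTT[T>G]	0.00260416666666667	0.00260416666666667	0.0026041678058947
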