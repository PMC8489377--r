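stage,key,ofv
base,,715.776
maturation,I,632.709
maturation,II,637.799
maturation,III,663.949
maturation,IV,646.078
maturation,V,671.471
covariates,WT,632.709
covariates,COMED+WT,631.345
covariates,SEX+WT,631.858
covariates,AGE+WT,632.462
covariates,HT+WT,628.091
covariates,ALT+WT,632.706
covariates,AST+WT,632.708
covariates,BUN+WT,626.547
covariates,SCR+WT,611.910
covariates,CYSC+WT,627.555
covariates,ALB+WT,632.315
covariates,TP+WT,632.552
covariates,EGFR+WT,620.829
covariates,BUN+SCR+WT,610.667
covariates,EGFR+SCR+WT,606.684
covariates,HT+SCR+WT,606.057
covariates,CYSC+SCR+WT,609.149
covariates,EGFR+HT+SCR+WT,603.087
covariates,HT+SCR,688.498
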