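set,group,sign,pka
bjellqvist,Nterm,pos,7.50
bjellqvist,Cterm,neg,3.55
bjellqvist,C,neg,9.00
bjellqvist,D,neg,4.05
bjellqvist,E,neg,4.45
bjellqvist,H,pos,5.98
bjellqvist,K,pos,10.00
bjellqvist,R,pos,12.00
bjellqvist,Y,neg,10.00
emboss,Nterm,pos,8.60
emboss,Cterm,neg,3.60
emboss,C,neg,8.50
emboss,D,neg,3.90
emboss,E,neg,4.10
emboss,H,pos,6.50
emboss,K,pos,10.80
emboss,R,pos,12.50
emboss,Y,neg,10.10
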