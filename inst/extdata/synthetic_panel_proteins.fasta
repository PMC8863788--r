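>HIGHPI_SYNTH_01 synthetic illustrative sequence, lysine/arginine-rich (high pI); not a natural protein
MKRKLAKVGRKSLNKAARQWTKHLVKRGMKPLSKAVRHNGKKLTSRWAKQGLKKVSNRLA
KTMGRKHPLAKSVRKWLNQAGKRLTKSA
>HIGHPI_SYNTH_02 synthetic illustrative sequence, histidine/arginine-rich (high pI); not a natural protein
MAHRLSKHGVRQWTNHLAKRGMHPLSRAVKHNGHRLTSKWAQHGLRKVSNHLAKTMGHRH
PLAKSVRHWLNQAGHRLTRSAHKVGQRL
>LOWPI_SYNTH_01 synthetic illustrative sequence, aspartate/glutamate-rich (low pI); not a natural protein
MDEDLAEVGDESLNDAAEQWTDSLVEDGMEPLSDAVENNGEDLTSEWADQGLEEVSNDLA
ETMGDESPLADSVEEWLNQAGEDLTDSA
>LOWPI_SYNTH_02 synthetic illustrative sequence, acidic with scattered tyrosines (low pI); not a natural protein
MSEDYAEVGDYSLNDAAEQWTDSYVEDGMEPLSDAVENNGEDYTSEWADQGLEEVSNDYA
ETMGDESPYADSVEEWLNQAGEDYTDSA
>NEUTRAL_SYNTH_01 synthetic illustrative sequence, balanced composition (near-neutral pI); not a natural protein
MASKLDEVGAQSLNTAARQWTDSLVKDGMEPLSHAVENNGKDLTSRWAEQGLTKVSNDLA
KTMGAESPLAHSVEQWLNRAGTDLTESA
>NEUTRAL_SYNTH_02 synthetic illustrative sequence, balanced with cysteine pair (near-neutral pI); not a natural protein
MASCLDKVGAQSLNTAAREWTDSLVKDGMCPLSHAVENNGKDLTSRWAEQGLTKVSNDLA
ETMGAKSPLAHSVEQWLNRAGTDLTRSA
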