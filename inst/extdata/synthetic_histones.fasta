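>H3 synthetic N-terminal tail (canonical residues 1-40)
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHR
>H4 synthetic N-terminal tail (R3 replaced by G to model a residue absent from the target species)
SGGGKGGKGLGKGGAKRHRKVLRDNIQGIT
>H2A synthetic N-terminal tail (canonical residues 1-30)
SGRGKQGGKARAKAKTRSSRAGLQFPVGRV
>H2B synthetic N-terminal tail
PEPAKSAPAPKKGSKKAVTKTQKKDGKKRR
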