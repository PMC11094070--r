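>Nat
TAAGATGAGAGTTGAGGAGAGTTATCCAAGCTATAGGGCCCTTCAGTATAGTAGTGTAAGTAGATAGTGGA
>ZZ
TAAGATGAGAGTTGAGGAGAGTTATCCAAGZTATAGGGCZZTTCAGTATAGTAGTGTAAGTAGATAGTGGA
>ZP-1
TAAGATGAGAGTTGAGGAGAGTTACGTGZACGCPTPGTCAZCACAGTATAGTAGTGTAAGTAGATAGTGGA
>ZP-2
TAAGATGAGAGTTGAGGAGAGTTATCAPCGTAGCAZPCTTPTZATGTATAGTAGTGTAAGTAGATAGTGGA
>C-Ran
TAAGATGAGAGTTGAGGAGAGTTATNNNCNNNGTATAGTAGTGTAAGTAGATAGTGGA
>Z-Ran
TAAGATGAGAGTTGAGGAGAGTTATNNNZNNNGTATAGTAGTGTAAGTAGATAGTGGA
>P-Ran
TAAGATGAGAGTTGAGGAGAGTTATNNNPNNNGTATAGTAGTGTAAGTAGATAGTGGA
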