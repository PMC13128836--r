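label	formula	volume
C0	NA	1610.5
C2	C2HF3O2	1757.5
C3	C3HF5O2	1831
C4	C4HF7O2	1904.5
C5	C5HF9O2	1978
C6	C6HF11O2	2051.5
C7	C7HF13O2	2125
C8	C8HF15O2	2198.5
C9	C9HF17O2	2272
3H	C3H2F4O2	1821.5
5H	C5H2F8O2	1968.5
7H	C7H2F12O2	2115.5
3Cl	C3HClF4O2	1838
FTA	C6H5F7O2	2010
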