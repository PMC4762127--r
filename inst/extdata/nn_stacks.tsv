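# Nearest-neighbor helix parameters (Turner 2004 set), kcal/mol.
# stack XW/YZ denotes 5'-X W-3' paired with 3'-Y Z-5'.
# dg37: free energy at 37 C; dh: enthalpy. init: duplex initiation;
# terminal_au: penalty per helix end closed by A-U or G-U.
stack	dg37	dh
CG/GC	-2.4	-10.6
CC/GG	-3.3	-13.4
CU/GG	-2.1	-12.1
CG/GU	-1.4	-5.6
CU/GA	-2.1	-10.5
CA/GU	-2.1	-10.4
GG/CC	-3.3	-13.4
GC/CG	-3.4	-14.9
GU/CG	-2.5	-12.6
GG/CU	-1.5	-8.3
GU/CA	-2.2	-11.4
GA/CU	-2.4	-12.4
GG/UC	-2.1	-12.1
GC/UG	-2.5	-12.6
GU/UG	1.3	-14.6
GG/UU	-0.5	-13.5
GU/UA	-1.4	-8.8
GA/UU	-1.3	-12.8
UG/GC	-1.4	-5.6
UC/GG	-1.5	-8.3
UU/GG	-0.5	-13.5
UG/GU	0.3	-9.3
UU/GA	-0.6	-3.2
UA/GU	-1	-7
AG/UC	-2.1	-10.5
AC/UG	-2.2	-11.4
AU/UG	-1.4	-8.8
AG/UU	-0.6	-3.2
AU/UA	-1.1	-9.4
AA/UU	-0.9	-6.8
UG/AC	-2.1	-10.4
UC/AG	-2.4	-12.4
UU/AG	-1.3	-12.8
UG/AU	-1	-7
UU/AA	-0.9	-6.8
UA/AU	-1.3	-7.7
init	4.1	3.6
terminal_au	0.5	3.7
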