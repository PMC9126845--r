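p5	ref	p3	alt	rate
A	C	A	A	1.1e-08
C	C	A	A	1.15e-08
G	C	A	A	1.15e-08
T	C	A	A	1.1e-08
A	T	A	A	1.1e-08
C	T	A	A	1.15e-08
G	T	A	A	1.15e-08
T	T	A	A	1.1e-08
A	C	C	A	1.15e-08
C	C	C	A	1.2e-08
G	C	C	A	1.2e-08
T	C	C	A	1.15e-08
A	T	C	A	1.15e-08
C	T	C	A	1.2e-08
G	T	C	A	1.2e-08
T	T	C	A	1.15e-08
A	C	G	A	1.15e-08
C	C	G	A	1.2e-08
G	C	G	A	1.2e-08
T	C	G	A	1.15e-08
A	T	G	A	1.15e-08
C	T	G	A	1.2e-08
G	T	G	A	1.2e-08
T	T	G	A	1.15e-08
A	C	T	A	1.1e-08
C	C	T	A	1.15e-08
G	C	T	A	1.15e-08
T	C	T	A	1.1e-08
A	T	T	A	1.1e-08
C	T	T	A	1.15e-08
G	T	T	A	1.15e-08
T	T	T	A	1.1e-08
A	T	A	C	4.4e-08
C	T	A	C	4.6e-08
G	T	A	C	4.6e-08
T	T	A	C	4.4e-08
A	T	C	C	4.6e-08
C	T	C	C	4.8e-08
G	T	C	C	4.8e-08
T	T	C	C	4.6e-08
A	T	G	C	4.6e-08
C	T	G	C	4.8e-08
G	T	G	C	4.8e-08
T	T	G	C	4.6e-08
A	T	T	C	4.4e-08
C	T	T	C	4.6e-08
G	T	T	C	4.6e-08
T	T	T	C	4.4e-08
A	C	A	G	1.1e-08
C	C	A	G	1.15e-08
G	C	A	G	1.15e-08
T	C	A	G	1.1e-08
A	T	A	G	1.1e-08
C	T	A	G	1.15e-08
G	T	A	G	1.15e-08
T	T	A	G	1.1e-08
A	C	C	G	1.15e-08
C	C	C	G	1.2e-08
G	C	C	G	1.2e-08
T	C	C	G	1.15e-08
A	T	C	G	1.15e-08
C	T	C	G	1.2e-08
G	T	C	G	1.2e-08
T	T	C	G	1.15e-08
A	C	G	G	1.15e-08
C	C	G	G	1.2e-08
G	C	G	G	1.2e-08
T	C	G	G	1.15e-08
A	T	G	G	1.15e-08
C	T	G	G	1.2e-08
G	T	G	G	1.2e-08
T	T	G	G	1.15e-08
A	C	T	G	1.1e-08
C	C	T	G	1.15e-08
G	C	T	G	1.15e-08
T	C	T	G	1.1e-08
A	T	T	G	1.1e-08
C	T	T	G	1.15e-08
G	T	T	G	1.15e-08
T	T	T	G	1.1e-08
A	C	A	T	4.4e-08
C	C	A	T	4.6e-08
G	C	A	T	4.6e-08
T	C	A	T	4.4e-08
A	C	C	T	4.6e-08
C	C	C	T	4.8e-08
G	C	C	T	4.8e-08
T	C	C	T	4.6e-08
A	C	G	T	1.15e-07
C	C	G	T	1.2e-07
G	C	G	T	1.2e-07
T	C	G	T	1.15e-07
A	C	T	T	4.4e-08
C	C	T	T	4.6e-08
G	C	T	T	4.6e-08
T	C	T	T	4.4e-08
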