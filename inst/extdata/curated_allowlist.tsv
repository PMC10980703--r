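# Compact example allow-list of variants with prior reports in curated mtDNA
# databases (well-established phylotree backbone polymorphisms and confirmed
# pathogenic variants). Substitute a full database export for production use;
# membership is exact (pos, alt) match, ref is rCRS.
pos	ref	alt	note
73	A	G	common D-loop polymorphism
146	T	C	common D-loop polymorphism
152	T	C	common D-loop polymorphism
195	T	C	common D-loop polymorphism
263	A	G	near-universal polymorphism
489	T	C	haplogroup M marker
750	A	G	near-universal polymorphism
1438	A	G	near-universal polymorphism
1719	G	A	haplogroup I/X marker
2706	A	G	haplogroup marker
3010	G	A	haplogroup H1/J1 marker
3460	G	A	LHON primary mutation
4216	T	C	haplogroup J/T marker
4769	A	G	near-universal polymorphism
4917	A	G	haplogroup T marker
7028	C	T	haplogroup marker (non-H)
8860	A	G	near-universal polymorphism
10398	A	G	haplogroup I/J/K marker
11251	A	G	haplogroup J/T marker
11719	G	A	haplogroup marker
11778	G	A	LHON primary mutation (MT-ND4)
12372	G	A	haplogroup U/K marker
13368	G	A	haplogroup T marker
13708	G	A	haplogroup J marker
14484	T	C	LHON primary mutation
14766	C	T	haplogroup marker (non-HV)
15326	A	G	near-universal polymorphism
16069	C	T	haplogroup J marker
16126	T	C	haplogroup J/T marker
16189	T	C	common D-loop polymorphism
16224	T	C	haplogroup K marker
16311	T	C	common D-loop polymorphism
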