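ps_index	ps_name	lineage_token
1	cellular organisms	cellular organisms
2	Eukaryota	Eukaryota
3	Opisthokonta	Opisthokonta
4	Fungi	Fungi
5	Dikarya	Dikarya
6	Ascomycota	Ascomycota
7	saccharomyceta	saccharomyceta
8	Pezizomycotina	Pezizomycotina
9	leotiomyceta	leotiomyceta
10	Sordariomycetes	Sordariomycetes
11	Sordariomycetidae	Sordariomycetidae
12	Sordariales	Sordariales
13	Sordariaceae	Sordariaceae
14	Sordaria	Sordaria
15	Sordaria macrospora	Sordaria macrospora
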