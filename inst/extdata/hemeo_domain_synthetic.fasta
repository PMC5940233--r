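>hemeo_syn_1
QLAEALPEAVREVHTKADNTPFMFYFLKGQLSLEQRFRLLLSLYEVESKLEEEMDFNPQH
>hemeo_syn_2
NLEEALKEATREVHTKAENTPFMFGFLIGELSVRQYKRLELPCYEVYSALEEEMDRNPQH
>hemeo_syn_3
NLAEALKEATREVHTKAENTPFMGGFLKGQLSLEVYKRLLLSLYEVYSATEEEMDRNPQH
>hemeo_syn_4
NAHEKLKEANREVHTKAENTPFMKGFLKGQLSLEQYKKLYLSLYEVYSALETEEDRNPQL
>hemeo_syn_5
NLAEALKEATREVHTCAENTPFMKGFLKFQLSLEQYVRLLLSLYEVYSALEEEMDRNPQH
>hemeo_syn_6
NLAEELKEATREVHTKAENTPFMKGFLKGQLSLEQYKRLLLSLYEHYSILEEEMDRNPQH
>hemeo_syn_7
NLAEALKEATRENHTGAESTPFMKGFTKGQLILEQYKRLLLSLYEVYSALEEKMDRNPQH
>hemeo_syn_8
NLAELLKELTRESMTKAENTPFMKGFLKGQLSLEQYKRLLLSLYEVYSALEEEMARNPQH
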