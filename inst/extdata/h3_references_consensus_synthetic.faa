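>plant_H3.1 mature plant (Arabidopsis-type) H3.1 consensus, assembled in-package (synthetic)
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRFRPGTVALREIRKYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSSAVAALQEAAEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
>plant_H3.3 mature plant (Arabidopsis-type) H3.3 consensus, assembled in-package (synthetic)
ARTKQTARKSTGGKAPRKQLATKAARKSAPTTGGVKKPHRYRPGTVALREIRKYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSHAVLALQEAAEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
>animal_H3.1 mature animal (human-type) H3.1 consensus, assembled in-package (synthetic)
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
>animal_H3.3 mature animal (human-type) H3.3 consensus, assembled in-package (synthetic)
ARTKQTARKSTGGKAPRKQLATKAARKSAPSTGGVKKPHRYRPGTVALREIRRYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSAAIGALQEASEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
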