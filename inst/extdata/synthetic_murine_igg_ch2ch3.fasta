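# Synthetic stand-in CH2-CH3 (Fc constant region) sequences for murine
# IgG subclasses. Generated once with a fixed seed at realistic
# amino-acid composition and inter-subclass divergence; NOT database
# sequences. Supply real constant-region FASTA for production use.
>IgG1 species=mouse region=CH2-CH3 synthetic=true
LGKIVKNFLEQELEIEDVEDLKDARGDFKALLALPTRSNKQMPVAIGPSMGLVAIIESYA
DYDQVKGMPLGERQLHFHDDAVLNILITFKMNLSAQAVVKNIPQRYISLGFLRDCRFRGA
GWELVLLRVLNDEELDTKFKEPTPERIRVLIPELADKKVTTNAERGLFRAEPESDSPNNI
NLKIGATRGRSHLFPSALPFGDYGHFRHMSEPGLIVAP
>IgG2a species=mouse region=CH2-CH3 synthetic=true
LGKIKKNFLEQEASIEDVEDLKNARGDFTARLALGMPSNKQMPVAIGFSMGLVAIGQSYA
RYDQVKGMKAGERILHFHDRAVKCTMIPVKMNTEAVNVVKNLDQRYAATVFERDCRRAGS
TWRIVYIRFLMDEEGDTKKEEPTIERIRHLIPEGADDDLTTNAARGVRKAETESDFVAKI
NLKIALTRGRSELFPAALPFENMGHFPHLSEPLLRVAP
>IgG2b species=mouse region=CH2-CH3 synthetic=true
LGKIVKQFLEQEAEIEDVEDLKDARGDQNARLALPIRSTKQMKVALLQSMGLNAIIASYA
RYKQVKGMKAGERQLHFHDDAVLCMLIFVKMNTSAVAVVKNMPQRYAALGFERDCRSEGM
TWRIVYIRALMDGEYDTKFKEPTPERIRHLKPPGPDKDDTINAKRGHFRAEPESDFPNKI
FLTIGFTRGRSELFPSQLPFVNFGHFRHMSEPLLDVLP
>IgG3 species=mouse region=CH2-CH3 synthetic=true
LGKIVKNFLEQEAEIEIVELLKDARGIFAARLLLLRRSNKQDLVAITQSTLLVALIQSYA
RYDQYKGMKAGEMQLHFHDDAVLGPTIFVKMNTSATAVVKNIPQRYAALGFCRDCNSRGM
TWRDVGIRVLMDEELITKFKEPTIERIRHLHPEGADKDVTTNTKRGEFRAEPESDFPNKI
NLKIGATRGRSELFPSALPFENYGHFRGMSEPLGIVAP
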