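# Systemic anticancer therapy lexicon: one lowercase phrase per line.
# Seeded with common cytotoxic, endocrine, targeted, and immunotherapy
# agents plus generic therapy terms; extend freely.
chemotherapy
chemo
carboplatin
cisplatin
oxaliplatin
taxol
paclitaxel
docetaxel
gemcitabine
folfox
folfiri
xeliri
xelox
5-fu
5-fu/leucovorin
leucovorin
fluorouracil
capecitabine
doxorubicin
cytoxan
cyclophosphamide
fludarabine
rituxan
rituximab
avastin
bevacizumab
ipilimumab
nivolumab
pembrolizumab
anastrozole
arimidex
tamoxifen
letrozole
trastuzumab
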