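>DH44-1_synthetic synthetic stand-in, 13 amidated peptide copies
MKFLVLLALVILAVQHSHAISAMHALPDALSPELAAGKRISAMHNLPDALSLELAAGKRI
SAMHVLPNALSQELAAGKRISHMHNLPDAFSQELAAGKRISAMHILPDALSQELAAGKRI
SATHNLPDAFSQLLAAGKRISSMHNYPDALSQELAAGKRISAMHNLPDDLSQELAAGKRI
SAMENLPDALSQELAAGKRISANHNLPTADSQELAAGKRISAMHNSPDALSQALAAGKRI
SAMHNLPDALGQYLAAGKRISAMHNLPDAISQELAAGKRDE
>DH44-2_synthetic synthetic stand-in, 16 amidated peptide copies
MRVLLFAVLLIVAFAQNSNAISGMHNLPDALSQMLAAGKRISAMHNMPDALSQSIAAGKR
ISAMHNLPDALQQELAAGKRISAMHNLIDALSQELAAGKRISAMMNQPDALSQSLAAGKR
ISAMHNLPDASSQELAAGKRISGMHNLPDALSQELAAGKRISAMHGLPDALSQELAAGKR
ISAMHVLPDALSQELAAGKRISAMHNSPDALSQELAAGKRISLMHNLPDDYSQELAAGKR
ISAMQNLPPALSQELAAGKRISAIHNLTDALSNELAAGKRISAMHNLPDALSQEQAAGKR
ISAMHNLPDALSEELAAGKRISAMHNLPILLSQELAAGKRDE
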