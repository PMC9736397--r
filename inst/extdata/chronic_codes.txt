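# Editable chronic-condition indicator list (three-character ICD-10
# categories). One code per line; '#' starts a comment. This default list
# covers the cardiometabolic conditions and chapter-spread chronic
# conditions used by the synthetic generator; replace it with your own
# dictionary for real data.
B18  # chronic viral hepatitis
C04
C18
C77
C78
C79
C80
D68  # coagulation defects
D69
E02
E04
E06
E11  # type 2 diabetes mellitus
E16
E22
E66  # obesity
E78  # lipoprotein metabolism disorders
E83
E89
G25
G47  # sleep disorders
G62
H25
H35
H90
I07
I10  # essential hypertension
I20
I21
I25
I27
I34
I36
I44
I47
I48
I49
I50  # heart failure
I51
I65
I70
I71
I74
J32
J43
J44
J47
J84
K74
K75
K76
K90
M06
M41
M47
M81
N03
N18  # chronic renal failure
N25
N26
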