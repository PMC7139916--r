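>FourEBP1_region synthetic assembled fragment (local coordinates)
AIPATRRVVLGDGVQLPPGDYSTTPGGTLFSTTPGGTRIIYDRKFLMECRNSPVTKTPPR
DLPTIPGVTSPSSDEPPMEASQSHLRNSPEDKRAGGEESQFEMDI
>CMET_region synthetic assembled fragment (local coordinates)
GLNTRDMYDKEYYSVHNKTGAKLQR
>RPS6_region synthetic assembled fragment (local coordinates)
IAKRRRLSSLRASTSKSESSQK
>MTOR_region synthetic assembled fragment (local coordinates)
ANQRTRTDSYSAGQSVEILDGVELGEPAHKTLK
>CTNNB1_region synthetic assembled fragment (local coordinates)
AVKRLSVELTSSLFRTEQ
>AKT1_region synthetic assembled fragment (local coordinates)
GATVRRPHFPQFSYSASGTA
>BAD_region synthetic assembled fragment (local coordinates)
AELRSRHSSYPAGTEDDEGMGEEPSPFRGRA
>ERK2_region synthetic assembled fragment (local coordinates)
SGLRVADPDHDHTGFLTEYVATRWYR
>ERK1_region synthetic assembled fragment (local coordinates)
SGLRIADPEHDHTGFLTEYVATRWYR
>STAT3_region synthetic assembled fragment (local coordinates)
EALKYCRPESQEHPEADPGSAAPYLKTK
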