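member	note
NETO2	previously established partner absent from the ME-AP screen
GRIK2	previously established partner absent from the ME-AP screen
EPB41L1	previously established partner absent from the ME-AP screen
ARHGEF7	previously established partner absent from the ME-AP screen
MYCBP2	previously established partner absent from the ME-AP screen
GABBR1	previously established partner absent from the ME-AP screen
GRM1	previously established partner absent from the ME-AP screen
GRM5	previously established partner absent from the ME-AP screen
RAB11A	previously established partner absent from the ME-AP screen
PRKCA	previously established partner absent from the ME-AP screen
WNK1	previously established partner absent from the ME-AP screen
STK39	previously established partner absent from the ME-AP screen
OXSR1	previously established partner absent from the ME-AP screen
SLC12A9	previously established partner absent from the ME-AP screen
LITPART15	synthetic placeholder for an unpublished list member
LITPART16	synthetic placeholder for an unpublished list member
LITPART17	synthetic placeholder for an unpublished list member
LITPART18	synthetic placeholder for an unpublished list member
LITPART19	synthetic placeholder for an unpublished list member
LITPART20	synthetic placeholder for an unpublished list member
LITPART21	synthetic placeholder for an unpublished list member
LITPART22	synthetic placeholder for an unpublished list member
LITPART23	synthetic placeholder for an unpublished list member
LITPART24	synthetic placeholder for an unpublished list member
LITPART25	synthetic placeholder for an unpublished list member
LITPART26	synthetic placeholder for an unpublished list member
LITPART27	synthetic placeholder for an unpublished list member
LITPART28	synthetic placeholder for an unpublished list member
LITPART29	synthetic placeholder for an unpublished list member
LITPART30	synthetic placeholder for an unpublished list member
LITPART31	synthetic placeholder for an unpublished list member
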