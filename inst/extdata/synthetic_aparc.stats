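# Table of FreeSurfer cortical parcellation anatomical statistics
# subjectname synthetic_subject
# hemi lh
# This file is a small synthetic example in the aparc.stats text dialect,
# constructed for testing the parser; the numbers are not from any real scan.
# NTableCols 10
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd
bankssts                 1500  1000  2600 2.40 0.45 0.12 0.03  12  1.5
cuneus                   2200  1500  3100 1.90 0.40 0.14 0.04  20  2.4
precuneus                6100  4100  9500 2.30 0.50 0.13 0.03  55  6.0
superiorfrontal         11000  7600 20400 2.70 0.52 0.12 0.03  90 10.5
temporalpole              700   500  2100 3.50 0.66 0.15 0.05   9  1.2
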