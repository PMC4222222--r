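# Title Segmentation Statistics
# generating_program mri_segstats
# SUBJECTS_DIR /synthetic
# subjectname synthetic_subject
# This file is a small synthetic example in the aseg.stats text dialect,
# constructed for testing the parser; the numbers are not from any real scan.
# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1150000.0, mm^3
# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1600000.000000, mm^3
# NTableCols 10
# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange
  1   4   900    900.0  Left-Lateral-Ventricle   25.0  10.0   5.0  90.0  85.0
  2  11  1750   1750.0  Left-Caudate             75.0   8.0  40.0 105.0  65.0
  3  12  2050   2050.0  Left-Putamen             82.0   6.0  50.0 105.0  55.0
  4  17  1800   1800.0  Left-Hippocampus         70.0   9.0  30.0 100.0  70.0
  5  43  1100   1100.0  Right-Lateral-Ventricle  25.0  10.0   5.0  90.0  85.0
  6  50  1750   1750.0  Right-Caudate            75.0   8.0  40.0 105.0  65.0
  7  51  1950   1950.0  Right-Putamen            82.0   6.0  50.0 105.0  55.0
  8  53  1700   1700.0  Right-Hippocampus        70.0   9.0  30.0 100.0  70.0
  9  24   950    950.0  CSF                      40.0  12.0  10.0  80.0  70.0
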