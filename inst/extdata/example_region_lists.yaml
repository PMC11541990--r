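genome: GRCh38
trisomy_coverage: 0.8
canonical:
- chrom: chr6
  arm: q
  type: loss
  rule: arm_overlap
- chrom: chr11
  arm: q
  type: loss
  rule: arm_overlap
- chrom: chr12
  type: gain
  rule: whole_chromosome
- chrom: chr13
  arm: q
  type: loss
  rule: arm_overlap
- chrom: chr17
  arm: p
  type: loss
  rule: arm_overlap
- chrom: chr13
  arm: q
  type: cnn_loh
  rule: anchor
  anchor_start: 5.0049119e+07
  anchor_end: 5.0049201e+07
driver_candidates:
- chrom: chr13
  start: 4.99e+07
  end: 5.01e+07
  type: loss
- chrom: chr11
  start: 1.082e+08
  end: 1.084e+08
  type: loss
- chrom: chr17
  start: 7500000.0
  end: 7700000.0
  type: loss
- chrom: chr6
  start: 1.06e+08
  end: 1.08e+08
  type: loss
- chrom: chr8
  start: 100000.0
  end: 4.0e+07
  type: loss
- chrom: chr2
  start: 100000.0
  end: 6.0e+07
  type: gain
- chrom: chr10
  start: 1.02e+08
  end: 1.04e+08
  type: loss
- chrom: chr13
  start: 4.0e+07
  end: 1.14e+08
  type: cnn_loh
- chrom: chr12
  start: 100000.0
  end: 1.332e+08
  type: gain
lymphoid:
- chrom: chr11
  arm: q
  type: loss
- chrom: chr13
  arm: q
  type: loss
- chrom: chr17
  arm: p
  type: loss
- chrom: chr12
  type: gain
- chrom: chr14
  arm: q
  type: cnn_loh
- chrom: chr22
  arm: q
  type: loss
arm_table:
  chr1:
    length: 2.4895642e+08
    centromere: 1.234e+08
  chr2:
    length: 2.4219353e+08
    centromere: 9.39e+07
  chr3:
    length: 1.9829556e+08
    centromere: 9.09e+07
  chr4:
    length: 1.9021456e+08
    centromere: 5.0e+07
  chr5:
    length: 1.8153826e+08
    centromere: 4.88e+07
  chr6:
    length: 1.7080598e+08
    centromere: 5.98e+07
  chr7:
    length: 1.5934597e+08
    centromere: 6.01e+07
  chr8:
    length: 1.4513864e+08
    centromere: 4.52e+07
  chr9:
    length: 1.3839472e+08
    centromere: 4.3e+07
  chr10:
    length: 1.3379742e+08
    centromere: 3.98e+07
  chr11:
    length: 1.3508662e+08
    centromere: 5.34e+07
  chr12:
    length: 1.3327531e+08
    centromere: 3.55e+07
  chr13:
    length: 1.1436433e+08
    centromere: 1.77e+07
  chr14:
    length: 1.0704372e+08
    centromere: 1.72e+07
  chr15:
    length: 1.0199119e+08
    centromere: 1.9e+07
  chr16:
    length: 9.0338345e+07
    centromere: 3.68e+07
  chr17:
    length: 8.3257441e+07
    centromere: 2.51e+07
  chr18:
    length: 8.0373285e+07
    centromere: 1.85e+07
  chr19:
    length: 5.8617616e+07
    centromere: 2.62e+07
  chr20:
    length: 6.4444167e+07
    centromere: 2.81e+07
  chr21:
    length: 4.6709983e+07
    centromere: 1.2e+07
  chr22:
    length: 5.0818468e+07
    centromere: 1.5e+07
  chrX:
    length: 1.560409e+08
    centromere: 6.05e+07
  chrY:
    length: 5.7227415e+07
    centromere: 1.04e+07
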