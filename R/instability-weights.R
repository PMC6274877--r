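# Guruprasad et al. (1990) dipeptide instability weight values (DIWV).
# Rows: first residue of the dipeptide; columns: second residue.
.DIWV <- matrix(c(
  1,44.94,-7.49,1,1,1,-7.49,1,1,1,1,1,20.26,1,1,1,1,1,1,1,
  1,1,20.26,1,1,1,33.6,1,1,20.26,33.6,1,20.26,-6.54,1,1,33.6,-6.54,24.68,1,
  1,1,1,1,-6.54,1,1,1,-7.49,1,1,1,1,1,-6.54,20.26,-14.03,1,1,1,
  1,44.94,20.26,33.6,1,1,-6.54,20.26,1,1,1,1,20.26,20.26,1,20.26,1,1,-14.03,1,
  1,1,13.34,1,1,1,1,1,-14.03,1,1,1,20.26,1,1,1,1,1,1,33.601,
  -7.49,1,1,-6.54,1,13.34,1,-7.49,-7.49,1,1,-7.49,1,1,1,1,-7.49,1,13.34,-7.49,
  1,1,1,1,-9.37,-9.37,1,44.94,24.68,1,1,24.68,-1.88,1,1,1,-6.54,1,-1.88,44.94,
  1,1,1,44.94,1,1,13.34,1,-7.49,20.26,1,1,-1.88,1,1,1,1,-7.49,1,1,
  1,1,1,1,1,-7.49,1,-7.49,1,-7.49,33.6,1,-6.54,24.64,33.6,1,1,-7.49,1,1,
  1,1,1,1,1,1,1,1,-7.49,1,1,1,20.26,33.6,20.26,1,1,1,24.68,1,
  13.34,1,1,1,1,1,58.28,1,1,1,-1.88,1,44.94,-6.54,-6.54,44.94,-1.88,1,1,24.68,
  1,-1.88,1,1,-14.03,-14.03,1,44.94,24.68,1,1,1,-1.88,-6.54,1,1,-7.49,1,-9.37,1,
  20.26,-6.54,-6.54,18.38,20.26,1,1,1,1,1,-6.54,1,20.26,20.26,-6.54,20.26,1,20.26,-1.88,1,
  1,-6.54,20.26,20.26,-6.54,1,1,1,1,1,1,1,20.26,20.26,1,44.94,1,-6.54,1,-6.54,
  1,1,1,1,1,-7.49,20.26,1,1,1,1,13.34,20.26,20.26,58.28,44.94,1,1,58.28,-6.54,
  1,33.6,1,20.26,1,1,1,1,1,1,1,1,44.94,20.26,20.26,20.26,1,1,1,1,
  1,1,1,20.26,13.34,-7.49,1,1,1,1,1,-14.03,1,-6.54,1,1,1,1,-14.03,1,
  1,1,-14.03,1,1,-7.49,1,1,-1.88,1,1,1,20.26,1,1,1,-7.49,1,1,-6.54,
  -14.03,1,1,1,1,-9.37,24.68,1,1,13.34,24.68,13.34,1,1,1,1,-14.03,-7.49,1,1,
  24.68,1,24.68,-6.54,1,-7.49,13.34,1,1,1,44.94,1,13.34,1,-15.91,1,-7.49,1,-9.37,13.34
), nrow = 20, byrow = TRUE, dimnames = list(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"), c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")))
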