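# Independent transcription of the poly-DL-alanine reference-rate
# model used as the oracle for intrinsic_rates(). Deliberately coded in
# a different style (parsed text table, explicit per-amide loop) and
# kept separate from the package implementation; the published
# constants are the same by construction.

oracle_side_chain <- utils::read.table(header = TRUE, text = "
res acid_own acid_next base_own base_next
A    0.00  0.00  0.00  0.00
C   -0.54 -0.46  0.62  0.55
D    0.90  0.58 -0.30 -0.18
E   -0.90  0.31 -0.51 -0.15
F   -0.52 -0.43 -0.24  0.06
G   -0.22  0.22  0.27  0.17
H    0.00  0.00 -0.10  0.14
I   -0.91 -0.59 -0.73 -0.23
K   -0.56 -0.29 -0.04  0.12
L   -0.57 -0.13 -0.58 -0.21
M   -0.64 -0.28 -0.01  0.11
N   -0.58 -0.13  0.49  0.32
P      NA -0.19    NA -0.24
Q   -0.47 -0.27  0.06  0.20
R   -0.59 -0.32  0.08  0.22
S   -0.44 -0.39  0.37  0.30
T   -0.79 -0.47 -0.07  0.20
V   -0.74 -0.30 -0.70 -0.14
W   -0.40 -0.44 -0.41 -0.11
Y   -0.41 -0.37 -0.27  0.05
", stringsAsFactors = FALSE)
rownames(oracle_side_chain) <- oracle_side_chain$res

# Returns k_int (1/s) for each residue; NA for position 1 and prolines.
oracle_kint <- function(sequence, pD = 8.0, temperature_K = 298.15) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  out <- rep(NA_real_, n)
  R_cal <- 1.9872
  for (i in 2:n) {
    if (res[i] == "P") next
    fa <- oracle_side_chain[res[i], "acid_own"] +
      oracle_side_chain[res[i - 1], "acid_next"]
    fb <- oracle_side_chain[res[i], "base_own"] +
      oracle_side_chain[res[i - 1], "base_next"]
    if (i == 2) { fa <- fa - 1.32; fb <- fb + 1.62 }
    if (i == n) { fa <- fa + 0.96; fb <- fb - 1.80 }
    k_acid <- 10^(1.62 + fa) * 10^(-pD) *
      exp(-14000 / R_cal * (1 / temperature_K - 1 / 293))
    k_base <- 10^(10.18 + fb) * 10^(pD - 15.05) *
      exp(-17000 / R_cal * (1 / temperature_K - 1 / 293))
    k_water <- 10^(-1.5 + fb) *
      exp(-19000 / R_cal * (1 / temperature_K - 1 / 293))
    out[i] <- (k_acid + k_base + k_water) / 60
  }
  out
}
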