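# Shared fixtures, built in code.

# Published multi-temperature binding constants (L/mol) for the two
# characterised inhibitors; inputs to the Van't Hoff fits.
table4_piboserod <- tibble::tibble(
  temperature_K = c(298, 304, 310),
  ka = c(8.595e4, 6.724e4, 4.912e4)
)
table4_rotigotine <- tibble::tibble(
  temperature_K = c(298, 304, 310),
  ka = c(5.084e4, 2.896e4, 1.469e4)
)

# Exact static-quenching titration at one temperature:
# F = F0 / (1 + Ksv * q) so the Stern-Volmer slope is Ksv exactly.
make_sv_series <- function(ksv, f0 = 1000,
                           q = seq(0, 50e-6, length.out = 7),
                           temperature_K = 298) {
  tibble::tibble(temperature_K = temperature_K, q_molL = q,
                 f = f0 / (1 + ksv * q))
}

# Brute-force AUC oracle: mean over all positive-negative pairs, ties 1/2.
pairwise_auc <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
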