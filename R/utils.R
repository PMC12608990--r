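# Vectorized content fingerprint (two weighted byte sums, hex-encoded) used
# to stamp run manifests; deterministic across platforms, not cryptographic.
content_hash <- function(x) {
  b <- as.numeric(serialize(x, NULL, version = 2L))
  w <- ((seq_len(256) * 2654435761) %% 65521) + 1
  m <- 2^31 - 1
  n <- length(b)
  h1 <- sum((b + 1) * rep_len(w, n)) %% m
  h2 <- sum((b + 7) * rep_len(rev(w), n)) %% m
  sprintf("%04x%04x%04x%04x",
          h1 %/% 65536, h1 %% 65536, h2 %/% 65536, h2 %% 65536)
}

# ggplot2 aesthetics referenced by bare name in report()
utils::globalVariables(c("day", "cumulative", "accuracy", "algorithm"))
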