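# Shared fixtures and small numerical helpers.

# Minimal capture table builder.
cap_rows <- function(tag, species, occasion, section, len = 80) {
  data.frame(tag_id = tag, species = species, occasion = occasion,
             section = section, total_length_mm = len,
             stringsAsFactors = FALSE)
}

# 15 occasions at 93-day intervals, as in the survey design.
std_occasions <- function(n = 15, gap = 93) {
  make_occasions(as.Date("2020-11-01") + gap * (seq_len(n) - 1))
}

# Monte Carlo standard error from one pooled draw vector, by batch means
# (accounts for autocorrelation left after thinning).
mcse <- function(x, n_batches = 25) {
  bs <- floor(length(x) / n_batches)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(bm) / sqrt(n_batches)
}

# Wrap a pooled sample matrix as the minimal object rhat() consumes.
fake_draws <- function(chain_list, parameter = "theta") {
  n <- length(chain_list[[1]])
  arr <- array(NA_real_, c(length(chain_list), n, 1),
               dimnames = list(NULL, NULL, parameter))
  for (ch in seq_along(chain_list)) arr[ch, , 1] <- chain_list[[ch]]
  structure(list(draws = arr, parameters = parameter), class = "dom_draws")
}
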