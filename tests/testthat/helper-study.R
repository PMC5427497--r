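# Desk-scale ordering studies are expensive (a full train/evaluate cycle
# per seed), so they are computed once per test session and shared by
# every test that needs them.

.study_cache <- new.env(parent = emptyenv())

get_ordering_studies <- function(n_seeds = 5) {
  key <- paste0("s", n_seeds)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- lapply(seq_len(n_seeds), function(s)
      ordering_study(seed = s, mixture = s == 1))
  }
  .study_cache[[key]]
}
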