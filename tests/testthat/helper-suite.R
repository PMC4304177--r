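# The randomized cleaning suite is shared by several test files; build it
# once per session and cache it.
.suite_cache <- new.env(parent = emptyenv())

get_clean_suite <- function(n = 200L, seed = 101L) {
  key <- sprintf("s_%d_%d", n, seed)
  if (is.null(.suite_cache[[key]])) {
    .suite_cache[[key]] <- make_clean_suite(n, seed = seed)
  }
  .suite_cache[[key]]
}

get_cleaned_results <- function(n = 200L, seed = 101L) {
  key <- sprintf("r_%d_%d", n, seed)
  if (is.null(.suite_cache[[key]])) {
    suite <- get_clean_suite(n, seed)
    .suite_cache[[key]] <- lapply(suite, function(fx) {
      ch <- parse_pdb(fx$text)[[1]]
      list(fixture = fx, parsed = ch, result = clean_chain(ch))
    })
  }
  .suite_cache[[key]]
}
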