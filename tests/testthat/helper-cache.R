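# Cross-test cache so expensive Monte-Carlo cells are computed once per
# test run and shared between the test blocks that summarize them.
.goaldr_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.goaldr_test_cache[[key]]))
    .goaldr_test_cache[[key]] <- force(expr)
  .goaldr_test_cache[[key]]
}

fast_ctl <- function(...) goaldr_control(fast = TRUE, seed = 1L, ...)

# 20 selection-only runs on SoSt (n = 500, p = 20), shared by the
# selection-path and tuning tests.
sost_select_runs <- function() {
  cached("sost_select_20", {
    lapply(1:20, function(s) {
      d <- sim_drf_data("SoSt", n = 500, p = 20, rho = 0, eta = 2,
                        seed = 4000 + s)
      path <- selection_path(d$t, d$y, d$z)
      sel <- select_lambda(path, d$z, d$t)
      list(data = d, path = path, sel = sel)
    })
  })
}
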