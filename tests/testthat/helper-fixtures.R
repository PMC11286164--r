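# Shared fixtures. Default-thread simulations are cached per seed: several
# files inspect the same runs (headline strain, event log, curve analysis),
# and one run takes on the order of a second.

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_thread(default_kukulcania_config(),
                                         seed = seed)
  .sim_cache[[key]]
}

# single looped fibre in a bundle, explicit loops
single_loop_bundle <- function(thresholds, hidden, post_xc = 0.5,
                               law = linear_law(1), d = 1) {
  bundle(list(looped_element("L1", d, law, thresholds, hidden,
                             post_loop_critical_strain = post_xc)))
}

# closed-form opening strains under the reset rule: loop i (thresholds
# sorted ascending) opens at sum_{j<i}(t_j + h_j) + t_i
closed_form_openings <- function(thresholds, hidden) {
  ord <- order(thresholds)
  t <- thresholds[ord]
  h <- hidden[ord]
  cumsum(c(0, (t + h)[-length(t)])) + t
}

# minimal coupled thread: 1 uf-like looped fibre + 1 axial-like straight
# fibre receiving its slack
mini_coupled_config <- function(n_loops = 20, Cs = 0.999) {
  thread_config(list(
    list(name = "uf", count = 1L, rel_diameter = 1,
         law = list(linear = list(E = 7)),
         loops = list(count = as.integer(n_loops),
                      threshold = list(mean = 0.150, pm = 0.145),
                      hidden_length = list(mean = 0.038, pm = 0.002))),
    list(name = "axial", count = 1L, rel_diameter = 0.2,
         law = list(poly = list(c1 = 0.1, c3 = 5)), critical_strain = 0.5,
         coupling = list(sources = "uf", Cs = Cs))
  ))
}

# three equal-diameter looped fibres with widely spread thresholds: every
# loop opening produces a distinct, large relative force drop
equal_diameter_bundle <- function(seed = 1, n_loops = 10) {
  els <- lapply(1:3, function(i) {
    thr <- sample_pm(uniform_pm(1.5, 1.4), n_loops, substream_seed(seed, i, "t"))
    hid <- sample_pm(uniform_pm(0.3, 0), n_loops, substream_seed(seed, i, "h"))
    looped_element(paste0("L", i), 1, linear_law(1), thr, hid,
                   post_loop_critical_strain = 1)
  })
  bundle(els)
}
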