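# Shared synthetic sessions, built lazily and cached for the whole test run.
.session_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .session_cache)) {
    assign(name, builder(), envir = .session_cache)
  }
  get(name, envir = .session_cache)
}

test_geometry <- function() cached("geom", function() arena_geometry())

# 15-minute mixed session: 2 place, 1 directional, 1 conjunctive,
# 2 background cells; biased agent so all outcome types occur
small_session <- function() {
  cached("small", function() {
    geom <- test_geometry()
    truth <- dplyr::bind_rows(
      make_ground_truth(geom, n_place = 2, seed = 101),
      make_ground_truth(geom, n_directional = 1, n_conjunctive = 1, seed = 102),
      make_ground_truth(geom, n_background = 2, seed = 103)
    )
    truth$neuron <- seq_len(nrow(truth))
    simulate_session(truth, geom, duration = 900, n_trials = 27, seed = 105,
                     policy = "biased", p_correct = 0.7, p_timeout = 0.05)
  })
}

small_truth <- function() small_session()$truth

# brute-force local maxima with prominence (independent oracle for
# detect_events): scan every index, walk to nearest higher value on each side
oracle_peaks <- function(x, prom) {
  n <- length(x)
  out <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if ((i == 1L || x[i - 1L] < x[i]) && (j == n || x[j + 1L] < x[i]) &&
        !(i == 1L && j == n)) {
      left <- if (i == 1L) x[1L] else {
        seg <- x[1:(i - 1L)]
        higher <- which(seg > x[i])
        if (length(higher)) min(x[(max(higher)):(i - 1L)]) else min(seg)
      }
      right <- if (j == n) x[n] else {
        seg <- x[(j + 1L):n]
        higher <- which(seg > x[i])
        if (length(higher)) min(x[(j + 1L):(j + min(higher))]) else min(seg)
      }
      if (x[i] - max(left, right) >= prom) out <- c(out, i)
    }
    i <- j + 1L
  }
  out
}
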