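## Shared fixtures: the builtin pool, a default excitation/recruitment
## setup, and small constructors used across the test files.

the_pool <- load_pool()

## pipeline-default excitation: drive plateau covers [2000, 4000) exactly
steady_excitation <- function() {
  excitation_signal(delay_ms = 1000)
}

ns_firings <- function(seed, pool = the_pool) {
  generate_pool_firings(pool, steady_excitation(), recruitment_plan(pool), seed)
}

## wrap explicit pulse-time vectors as a firing_set
toy_firing_set <- function(..., duration_ms = 5000) {
  trains <- lapply(list(...), as.integer)
  if (is.null(names(trains)) || any(names(trains) == "")) {
    names(trains) <- paste0("MU", seq_along(trains))
  }
  structure(list(trains = trains, seed = NA_integer_,
                 duration_ms = duration_ms, provenance = "toy"),
            class = "firing_set")
}

## random sparse trains on the 1-ms grid for oracle comparisons
random_train <- function(n, lo = 2000, hi = 3999) {
  sort(sample(lo:hi, n))
}

steady_count <- function(fs) {
  vapply(fs$trains, function(t) sum(t >= 2000 & t < 4000), integer(1))
}
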