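# Shared fixtures, memoized across test files so the expensive objects
# (ground-truth traces, compiled objectives, reference optimizer runs) are
# built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, make) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(make()), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

fix_protocol <- function() fixture("protocol", standard_protocol)

fix_model <- function(id = "IKr") {
  fixture(paste0("model_", id), function() current_model(id))
}

fix_truth <- function(id = "IKr") {
  fixture(paste0("truth_", id), function() {
    generate_ground_truth(fix_model(id), fix_protocol())
  })
}

fix_objective <- function(id = "IKr") {
  fixture(paste0("objective_", id), function() {
    build_objective(fix_model(id), fix_protocol(), fix_truth(id))
  })
}

# Uniform random start within the space, redrawn until the cost is finite
# (wide spaces contain kinetically invalid vectors). Uses the caller's RNG.
draw_valid_start <- function(objective, space, max_tries = 1000) {
  for (k in seq_len(max_tries)) {
    p <- stats::runif(length(space$lower), space$lower, space$upper)
    if (is.finite(sse_cost(objective, p))) return(p)
  }
  stop("no kinetically valid start found")
}

# A small deterministic toy least-squares problem: residuals (p - target)
# scaled, with the residual function attached the way swarm/TRR code expects
# it on plain (non-trace) objectives.
toy_objective <- function(target = c(1, -2), scale = c(1, 3)) {
  res_fn <- function(p) scale * (p - target)
  obj <- function(p) sum(res_fn(p)^2)
  attr(obj, "residual_fn") <- res_fn
  obj
}

toy_space <- function(lower = c(-5, -5), upper = c(5, 5)) {
  list(lower = lower, upper = upper)
}
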