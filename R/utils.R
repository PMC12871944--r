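#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows bind_cols across n row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd quantile rnorm runif rbinom rpois plogis qlogis
#'   qnorm cor p.adjust t.test cor.test setNames
NULL

# Sentinel marking "sensor/item unavailable" throughout the pipeline.
SENTINEL <- -1

# Night window, half-open [22:00, 06:00), single local timezone.
NIGHT_START <- 22
NIGHT_END <- 6

is_night_hour <- function(hour) hour >= NIGHT_START | hour < NIGHT_END

#' @keywords internal
is_sentinel <- function(x) !is.na(x) & x == SENTINEL

# Population SD (divide by n); the package-wide convention for feature SDs.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Package-local cache for pure-but-expensive constructors.
.phenosense_cache <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package funnel their seed through this
#' helper so that identical seeds give identical results without disturbing
#' the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(as.integer(seed))
  code
}

# Derive a bounded child seed from a master seed and a stream index, so that
# repetitions/folds get reproducible but distinct RNG streams.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

stop_phenosense <- function(msg, class) {
  rlang::abort(msg, class = c(class, "phenosense_error"))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_phenosense(
      sprintf("`%s` must be a fraction in [0, 1].", name),
      "phenosense_config_error"
    )
  }
  invisible(x)
}

# Fast tibble constructor for hot loops (skips tibble()'s validation).
fast_tbl <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = if (length(cols)) length(cols[[1]]) else 0L)
}
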