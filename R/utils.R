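`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a class of the form
#' `dissolvenet_error_<name>` so callers can handle them selectively.
#' @noRd
dn_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("dissolvenet_error_", class),
                                     "dissolvenet_error"),
                      call = call))
}

dn_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("dissolvenet_warning_", class),
                                          "dissolvenet_warning")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that seeded package
#' functions never perturb the global RNG stream.
#' @noRd
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    dn_stop("`seed` must be a single finite number", "bad_seed")
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a base seed and a stream label.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

# Add a per-column vector to every row of a matrix (column-major recycling).
add_rowwise <- function(M, v) M + rep(v, each = nrow(M))

mul_rowwise <- function(M, v) M * rep(v, each = nrow(M))
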