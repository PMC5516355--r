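# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  if (x < lower) stop_field(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

#' Coerce class labels to an internal logical (is-positive) vector
#'
#' @param labels factor or character vector with exactly two observed classes
#'   (one class only is allowed when `allow_single = TRUE`).
#' @param positive the level treated as the positive class; defaults to the
#'   first level of `factor(labels)`.
#' @return logical vector with attributes `positive` and `negative`.
#' @noRd
as_binary_labels <- function(labels, positive = NULL, allow_single = FALSE) {
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  f <- factor(labels)
  lev <- levels(f)
  if (is.null(positive)) positive <- lev[1L]
  if (!positive %in% lev && !allow_single) {
    stop(sprintf("positive class '%s' not present in labels", positive),
         call. = FALSE)
  }
  if (length(lev) > 2L) {
    stop("labels must contain at most two classes", call. = FALSE)
  }
  if (length(lev) < 2L && !allow_single) {
    stop("labels must contain two classes", call. = FALSE)
  }
  is_pos <- as.character(f) == positive
  negative <- setdiff(lev, positive)
  structure(is_pos, positive = positive,
            negative = if (length(negative)) negative else NA_character_)
}

# deterministic per-stage seed derivation from one master seed; stays well
# below .Machine$integer.max for small master seeds
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 131L + stage) %% 2147483647)
}
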