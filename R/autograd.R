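# Reverse-mode automatic differentiation on a flat tape.
#
# Tensors are plain R arrays; an `ag_tensor` wraps an array in an environment
# so gradients can accumulate in place. Operations in nn-ops.R compute their
# value eagerly and, when a tape is active and some input requires a gradient,
# push a backward closure onto the tape. `ag_backward()` walks the tape in
# reverse. With no active tape every op degenerates to a plain array function,
# which is the inference path (nothing is cached).

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

#' Create a differentiable tensor
#'
#' Wraps an array so that gradient can accumulate on it during
#' [ag_backward()]. Network parameters are `ag_tensor`s with
#' `requires_grad = TRUE`.
#'
#' @param value numeric array.
#' @param requires_grad should a gradient be accumulated for this tensor?
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires <- requires_grad
  class(e) <- "ag_tensor"
  e
}

nn_param <- function(value) ag_tensor(value, requires_grad = TRUE)

is_ag <- function(x) inherits(x, "ag_tensor")

ag_val <- function(x) if (is_ag(x)) x$value else x

ag_requires <- function(x) is_ag(x) && isTRUE(x$requires)

#' Start recording operations on a fresh tape
#' @keywords internal
ag_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$records <- vector("list", 256L)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

ag_tape_active <- function() !is.null(.ag$tape)

ag_tape_clear <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$tape
  .ag$tape <- NULL
  on.exit(.ag$tape <- old, add = TRUE)
  expr
}

# Register an op result. `backward` receives the output gradient and must
# return a list of gradients aligned with `inputs` (NULL entries allowed).
ag_record <- function(value, inputs, backward) {
  t <- .ag$tape
  if (is.null(t) || !any(vapply(inputs, ag_requires, logical(1L)))) {
    return(value)
  }
  out <- ag_tensor(value, requires_grad = TRUE)
  n <- t$n + 1L
  if (n > length(t$records)) {
    t$records <- c(t$records, vector("list", length(t$records)))
  }
  t$records[[n]] <- list(inputs = inputs, output = out, backward = backward)
  t$n <- n
  out
}

#' Backpropagate from a scalar loss through the active tape
#'
#' Accumulates gradients into every recorded `ag_tensor` with
#' `requires_grad = TRUE` and clears the tape.
#'
#' @param loss an `ag_tensor` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag(loss))
  t <- .ag$tape
  if (is.null(t)) stop("no active tape; wrap the forward pass in ag_tape_start()")
  loss$grad <- 1
  for (i in rev(seq_len(t$n))) {
    rec <- t$records[[i]]
    gout <- rec$output$grad
    if (is.null(gout)) next
    grads <- rec$backward(gout)
    for (j in seq_along(rec$inputs)) {
      inp <- rec$inputs[[j]]
      if (ag_requires(inp) && !is.null(grads[[j]])) {
        inp$grad <- if (is.null(inp$grad)) grads[[j]] else inp$grad + grads[[j]]
      }
    }
    rec$output$grad <- NULL
  }
  ag_tape_clear()
  invisible(loss)
}

# Zero the gradients of a flat list of parameters.
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Recursively collect every ag_tensor in a nested list (parameter harvesting).
collect_params <- function(x, prefix = "") {
  if (is_ag(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    out <- list()
    for (i in seq_along(x)) {
      sub <- collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nms[[i]]))
      out <- c(out, sub)
    }
    return(out)
  }
  list()
}
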