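# Recursive path-model specification.
#
# Observed-variable path models: directed acyclic edges among observed
# variables, one free coefficient per edge, one free residual variance per
# endogenous variable and one free variance per exogenous variable.
# Residuals are uncorrelated (diagonal Psi).

#' Specify a recursive path model
#'
#' @param paths character vector of directed edges `"source -> target"`, or
#'   a two-column data frame / matrix with source and target columns.
#' @param variables optional character vector fixing the variable order;
#'   defaults to order of first appearance in `paths`. Variables not on any
#'   path may be added here (they become exogenous isolates).
#' @return A `path_model`: list with `variables`, `paths` (data frame
#'   `source`, `target`), `exogenous`, `endogenous`, `order` (a topological
#'   order), and `parameters` (the free-parameter registry: path coefficients
#'   named `"source->target"`, exogenous variances `"var:x"`, residual
#'   variances `"psi:y"`).
#' @examples
#' m <- path_model(c("x -> m", "m -> y", "x -> y"))
#' model_df(m)
#' @export
path_model <- function(paths, variables = NULL) {
  if (is.character(paths)) {
    parts <- strsplit(paths, "->", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("paths must look like \"source -> target\"", call. = FALSE)
    edges <- data.frame(source = trimws(vapply(parts, `[`, "", 1)),
                        target = trimws(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(paths, stringsAsFactors = FALSE)[, 1:2]
    names(edges) <- c("source", "target")
  }
  if (nrow(edges) && any(edges$source == edges$target))
    stop("self-loop path", call. = FALSE)
  if (anyDuplicated(paste(edges$source, edges$target)))
    stop("duplicate path", call. = FALSE)
  seen <- unique(c(rbind(edges$source, edges$target)))
  variables <- if (is.null(variables)) seen else {
    if (!all(seen %in% variables))
      stop("paths mention variables missing from `variables`", call. = FALSE)
    as.character(variables)
  }
  order <- .topo_order(variables, edges)   # errors on cycles
  endogenous <- intersect(variables, unique(edges$target))
  exogenous <- setdiff(variables, endogenous)
  pre <- function(prefix, x)   # paste0 pads zero-length args to ""
    if (length(x)) paste0(prefix, x) else character(0)
  params <- c(if (nrow(edges)) paste0(edges$source, "->", edges$target)
              else character(0),
              pre("var:", exogenous), pre("psi:", endogenous))
  structure(list(variables = variables, paths = edges,
                 exogenous = exogenous, endogenous = endogenous,
                 order = order, parameters = params),
            class = "path_model")
}

.topo_order <- function(variables, edges) {
  indeg <- stats::setNames(integer(length(variables)), variables)
  for (t in edges$target) indeg[t] <- indeg[t] + 1L
  out <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    kids <- edges$target[edges$source == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(out) != length(variables))
    stop("path diagram contains a cycle; only recursive (acyclic) models ",
         "are supported", call. = FALSE)
  out
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("<path_model> %d variables, %d paths, %d free parameters\n",
              length(x$variables), nrow(x$paths), length(x$parameters)))
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  if (nrow(x$paths))
    cat(paste0("  ", x$paths$source, " -> ", x$paths$target, collapse = "\n"),
        "\n")
  invisible(x)
}

#' Degrees of freedom of a path model
#'
#' Number of distinct covariance moments, p(p+1)/2, minus the number of free
#' parameters.
#'
#' @param model a [path_model()].
#' @return Integer degrees of freedom.
#' @export
model_df <- function(model) {
  stopifnot(inherits(model, "path_model"))
  p <- length(model$variables)
  as.integer(p * (p + 1) / 2 - length(model$parameters))
}

#' Read a path model from a YAML config
#'
#' The config lists `variables` (optional) and `paths` as
#' `"source -> target"` strings.
#'
#' @param path YAML file.
#' @return A [path_model()].
#' @export
read_path_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$paths)) stop("config must list `paths`", call. = FALSE)
  path_model(unlist(cfg$paths), variables = unlist(cfg$variables))
}

#' The anther-culture regeneration path model
#'
#' The five-variable recursive model linking Cu(II) concentration in the
#' induction medium (`cu`, the sole exogenous variable) to green plant
#' regeneration efficiency (`gpre`) through de novo CHH methylation
#' (`chh_dnmv`), CHH sequence variation (`chh_sv`) and the glutathione FTIR
#' band integral (`gsh`): eight paths, four residual variances, one exogenous
#' variance (13 free parameters, 2 degrees of freedom).
#'
#' @return A [path_model()].
#' @export
gpre_path_model <- function() {
  path_model(
    c("cu -> chh_dnmv",
      "chh_dnmv -> chh_sv",
      "cu -> chh_sv",
      "cu -> gsh",
      "cu -> gpre",
      "chh_sv -> gpre",
      "chh_dnmv -> gpre",
      "gsh -> gpre"),
    variables = c("cu", "chh_sv", "chh_dnmv", "gsh", "gpre"))
}

# Split a named theta vector into the coefficient matrix A (A[target, source])
# and diagonal Psi over model$variables.
.theta_matrices <- function(model, theta) {
  v <- model$variables
  if (is.null(names(theta)) || !setequal(names(theta), model$parameters))
    stop("theta must be named by the model's free-parameter registry",
         call. = FALSE)
  A <- matrix(0, length(v), length(v), dimnames = list(v, v))
  for (i in seq_len(nrow(model$paths)))
    A[model$paths$target[i], model$paths$source[i]] <-
      theta[[paste0(model$paths$source[i], "->", model$paths$target[i])]]
  psi <- numeric(length(v)); names(psi) <- v
  for (x in model$exogenous)  psi[x] <- theta[[paste0("var:", x)]]
  for (y in model$endogenous) psi[y] <- theta[[paste0("psi:", y)]]
  list(A = A, Psi = diag(psi, nrow = length(v)))
}

#' Model-implied covariance matrix
#'
#' For coefficient matrix A (rows = targets) and diagonal variance matrix
#' Psi of exogenous/residual variances, the implied covariance of the
#' observed variables is `(I - A)^-1 Psi (I - A)^-T`.
#'
#' @param model a [path_model()].
#' @param theta named numeric vector over `model$parameters`.
#' @return Symmetric implied covariance matrix.
#' @export
implied_sigma <- function(model, theta) {
  m <- .theta_matrices(model, theta)
  p <- length(model$variables)
  IAinv <- solve(diag(p) - m$A)
  sig <- IAinv %*% m$Psi %*% t(IAinv)
  dimnames(sig) <- list(model$variables, model$variables)
  (sig + t(sig)) / 2
}
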