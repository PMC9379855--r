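# Independent oracles used across the test files.

# Literal application of the two enzyme-sensitivity rules to a 4-digit code
# (aD, aR, kD, kR): KpnI cuts regardless of methylation, so k tracks the
# sequence; Acc65I needs an unmethylated site, so a = 1 implies k = 1;
# a band on Acc65I without the KpnI band in the same plant is contradictory.
enzyme_logic_classify <- function(code) {
  b <- as.integer(strsplit(code, "")[[1]])
  aD <- b[1]; aR <- b[2]; kD <- b[3]; kR <- b[4]
  if (aD == 1 && kD == 0) return("INCONSISTENT")
  if (aR == 1 && kR == 0) return("INCONSISTENT")
  if (kD == 0 && kR == 0) return("UNINFORMATIVE")
  if (kD != kR) return("SV")
  # sequence intact in both plants (kD = kR = 1): compare methylation
  if (aD == aR) return(if (aD == 1) "NO_CHANGE_UNMETHYLATED"
                       else "NO_CHANGE_METHYLATED")
  if (aD == 1 && aR == 0) return("DNMV")   # Acc65I band lost: gained methyl
  "DMV"                                    # Acc65I band gained: lost methyl
}

# Exact integral of amp * exp(-(x-c)^2 / (2 sigma^2)) over [a, b].
gauss_integral <- function(a, b, center, sigma, amp) {
  amp * sigma * sqrt(2 * pi) *
    (pnorm((b - center) / sigma) - pnorm((a - center) / sigma))
}

# Sum of coefficient products over all directed routes from src to tgt,
# by exhaustive depth-first enumeration (brute-force total effect).
enumerate_total_effect <- function(edges, coefs, src, tgt) {
  walk <- function(node, prod) {
    out <- edges$target[edges$source == node]
    tot <- 0
    for (k in out) {
      w <- prod * coefs[[paste0(node, "->", k)]]
      if (k == tgt) tot <- tot + w
      tot <- tot + walk(k, w)
    }
    tot
  }
  walk(src, 1)
}

# Random recursive path model on <= p variables with data generated from it.
random_path_model_data <- function(p = 5, n = 200, edge_prob = 0.5) {
  vars <- paste0("v", seq_len(p))
  edges <- character(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    if (runif(1) < edge_prob) edges <- c(edges, paste(vars[i], "->", vars[j]))
  if (!length(edges))
    edges <- paste(vars[1], "->", vars[2])
  model <- path_model(edges, variables = vars)
  coefs <- setNames(runif(nrow(model$paths), -1, 1),
                    paste0(model$paths$source, "->", model$paths$target))
  d <- as.data.frame(matrix(NA_real_, n, p, dimnames = list(NULL, vars)))
  for (x in model$exogenous) d[[x]] <- rnorm(n)
  for (y in intersect(model$order, model$endogenous)) {
    parents <- model$paths$source[model$paths$target == y]
    d[[y]] <- as.matrix(d[parents]) %*% coefs[paste0(parents, "->", y)] +
      rnorm(n, 0, runif(1, 0.5, 1.5))
  }
  list(model = model, data = d, coefs = coefs)
}

# A tiny two-platform marker table with known event composition.
crafted_marker_table <- function() {
  # 10 CHH loci: 6 no-change (4 unmeth, 2 meth), 2 SV, 1 DNMV, 1 DMV
  codes <- c("1111", "1111", "1111", "1111", "0011", "0011",
             "1010", "0010", "1011", "0111")
  ids <- sprintf("L%02d", seq_along(codes))
  bit <- function(pos) as.integer(substr(codes, pos, pos))
  rbind(
    data.frame(locus_id = ids, platform = "ACC", primer_extension = "AT",
               D = bit(1), R1 = bit(2), stringsAsFactors = FALSE),
    data.frame(locus_id = ids, platform = "KPN", primer_extension = "AT",
               D = bit(3), R1 = bit(4), stringsAsFactors = FALSE))
}
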