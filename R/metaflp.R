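# metAFLP donor/regenerant band-code scoring.
#
# Two AFLP platforms are run on the same DNA with isoschizomers that share a
# recognition site but differ in methylation sensitivity: Acc65I (ACC, blocked
# by cytosine methylation) and KpnI (KPN, cuts regardless of methylation).
# For each locus the presence (1) / absence (0) of the band is scored for the
# donor (D) and a regenerant (R) on both platforms, giving a 4-digit code
# (aD, aR, kD, kR) with 16 possible values 0000..1111.

#' Event classes of metAFLP band codes
#'
#' Labels for the outcome of classifying a donor/regenerant 4-digit band code:
#' no change (methylated or unmethylated site), sequence variation (`SV`),
#' demethylation (`DMV`), de novo methylation (`DNMV`), uninformative
#' (no band anywhere), or physically inconsistent (an Acc65I band without the
#' corresponding KpnI band in the same plant).
#'
#' @format Character vector of the seven class labels.
#' @export
metaflp_event_classes <- c(
  "NO_CHANGE_UNMETHYLATED", "NO_CHANGE_METHYLATED",
  "SV", "DMV", "DNMV", "UNINFORMATIVE", "INCONSISTENT"
)

# KpnI is methylation-insensitive, so k reflects sequence integrity of the
# restriction site; Acc65I requires an unmethylated site, so a = 1 means
# "present and unmethylated".  a = 1 with k = 0 is contradictory within one
# plant; kD != kR means the site sequence itself changed (SV); with the
# sequence intact in both plants, loss/gain of the Acc65I band is gain/loss
# of methylation (DNMV / DMV).
.metaflp_truth_table <- c(
  "0000" = "UNINFORMATIVE",
  "0001" = "SV",
  "0010" = "SV",
  "0011" = "NO_CHANGE_METHYLATED",
  "0100" = "INCONSISTENT",
  "0101" = "SV",
  "0110" = "INCONSISTENT",
  "0111" = "DMV",
  "1000" = "INCONSISTENT",
  "1001" = "INCONSISTENT",
  "1010" = "SV",
  "1011" = "DNMV",
  "1100" = "INCONSISTENT",
  "1101" = "INCONSISTENT",
  "1110" = "INCONSISTENT",
  "1111" = "NO_CHANGE_UNMETHYLATED"
)

#' The 16-code metAFLP classification table
#'
#' Returns the mapping from the 16 possible donor/regenerant band codes
#' (digit order: Acc65I donor, Acc65I regenerant, KpnI donor, KpnI
#' regenerant) to event classes. A reassignment map can be supplied to mirror
#' alternative published scoring schemes.
#'
#' @param reassign optional named character vector, e.g.
#'   `c("1100" = "SV")`, overriding individual codes. Values must be valid
#'   event-class labels.
#' @return Named character vector of length 16 (names are the codes).
#' @examples
#' metaflp_truth_table()[c("1011", "0111", "1010")]
#' @export
metaflp_truth_table <- function(reassign = NULL) {
  tab <- .metaflp_truth_table
  if (!is.null(reassign)) {
    if (is.null(names(reassign)) || !all(names(reassign) %in% names(tab)))
      stop("reassign must be named by 4-digit codes 0000..1111", call. = FALSE)
    if (!all(reassign %in% metaflp_event_classes))
      stop("reassign values must be valid event-class labels", call. = FALSE)
    tab[names(reassign)] <- reassign
  }
  tab
}

#' Encode donor/regenerant band presence as a 4-digit site code
#'
#' Builds the canonical code (aD, aR, kD, kR): Acc65I/MseI band for donor and
#' regenerant followed by the KpnI/MseI band for donor and regenerant. All
#' arguments are vectorized.
#'
#' @param acc_donor,acc_regenerant,kpn_donor,kpn_regenerant binary flags
#'   (0/1) for band presence on each platform.
#' @param context methylation context of the locus: `"CG"`, `"CHG"` or
#'   `"CHH"`.
#' @return A `site_code` data frame with columns `code` (4-character string)
#'   and `context` (factor).
#' @examples
#' encode_site(1, 0, 1, 1, "CHH")  # Acc65I band lost in regenerant -> "1011"
#' @export
encode_site <- function(acc_donor, acc_regenerant, kpn_donor, kpn_regenerant,
                        context) {
  flags <- cbind(acc_donor, acc_regenerant, kpn_donor, kpn_regenerant)
  if (!all(flags %in% c(0L, 1L)))
    stop("band presence flags must be 0 or 1", call. = FALSE)
  context <- as.character(context)
  if (!all(context %in% c("CG", "CHG", "CHH")))
    stop("context must be one of CG, CHG, CHH", call. = FALSE)
  code <- paste0(flags[, 1], flags[, 2], flags[, 3], flags[, 4])
  out <- data.frame(
    code = code,
    context = factor(context, levels = c("CG", "CHG", "CHH")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_code", class(out))
  out
}

#' Classify site codes into metAFLP event classes
#'
#' Total, deterministic classification of the 16 possible 4-digit codes by
#' the two enzyme-sensitivity rules (see [metaflp_truth_table()]).
#'
#' @param site a `site_code` data frame from [encode_site()], or a character
#'   vector of 4-digit codes.
#' @param table classification table, by default [metaflp_truth_table()].
#' @return Factor of event classes (levels [metaflp_event_classes]).
#' @examples
#' classify_code(c("1111", "1011", "0111", "1010", "0000", "1100"))
#' @export
classify_code <- function(site, table = metaflp_truth_table()) {
  codes <- if (is.data.frame(site)) site$code else as.character(site)
  if (!all(codes %in% names(table)))
    stop("invalid site code(s): ",
         paste(unique(setdiff(codes, names(table))), collapse = ", "),
         call. = FALSE)
  factor(unname(table[codes]), levels = metaflp_event_classes)
}

#' Assign a methylation context from a selective-primer 3' extension
#'
#' The selective primer's 3' end determines which cytosine context the
#' amplified restriction-site neighbourhood represents: a suffix `C-H-G`
#' (H = A, C or T) marks CHG; a suffix `CG` marks CG; a suffix of two bases
#' from \{A, T\} marks the asymmetric CHH context. When several patterns
#' match, the longest suffix wins (CHG before CG before CHH).
#'
#' @param primer_extension character vector of selective 3' extensions over
#'   the alphabet A, C, G, T.
#' @param on_unmatched `"error"` (default) to fail on an unclassifiable
#'   extension, or `"na"` to return `NA` with a warning so callers can
#'   exclude the locus.
#' @return Factor with levels `CG`, `CHG`, `CHH`.
#' @examples
#' assign_context(c("AT", "CG", "CAG"))
#' @export
assign_context <- function(primer_extension, on_unmatched = c("error", "na")) {
  on_unmatched <- match.arg(on_unmatched)
  x <- toupper(as.character(primer_extension))
  if (any(is.na(x) | nchar(x) == 0 | grepl("[^ACGT]", x)))
    stop("primer extensions must be non-empty strings over {A,C,G,T}",
         call. = FALSE)
  ctx <- rep(NA_character_, length(x))
  ctx[grepl("[AT][AT]$", x)] <- "CHH"
  ctx[grepl("CG$", x)]       <- "CG"
  ctx[grepl("C[ACT]G$", x)]  <- "CHG"   # longest suffix, applied last
  if (anyNA(ctx)) {
    bad <- unique(x[is.na(ctx)])
    msg <- paste0("unassigned context for extension(s): ",
                  paste(bad, collapse = ", "))
    if (on_unmatched == "error") stop(msg, call. = FALSE)
    warning(msg, "; loci excluded", call. = FALSE)
  }
  factor(ctx, levels = c("CG", "CHG", "CHH"))
}

#' Quantify tissue-culture-induced variation from classified site codes
#'
#' Computes the per-context percentages of sequence variation (SV),
#' demethylation (DMV) and de novo methylation (DNMV) events over all
#' informative sites, and their sum, the tissue-culture-induced variation
#' (TCIV). Informative sites are all codes except `UNINFORMATIVE` (0000);
#' `INCONSISTENT` codes stay in the denominator but, by default, in no event
#' class.
#'
#' @param codes a `site_code` data frame ([encode_site()]).
#' @param context which context to summarize (`"CG"`, `"CHG"`, `"CHH"`).
#' @param inconsistent_as_sv fold physically inconsistent codes into SV
#'   instead of leaving them unclassified (default `FALSE`).
#' @param table classification table passed to [classify_code()].
#' @return A one-row `variation_profile` data frame with columns `context`,
#'   `sv_pct`, `dmv_pct`, `dnmv_pct`, `tciv_pct`, `n_informative`,
#'   `n_inconsistent`.
#' @export
quantify_variation <- function(codes, context, inconsistent_as_sv = FALSE,
                               table = metaflp_truth_table()) {
  stopifnot(is.data.frame(codes), all(c("code", "context") %in% names(codes)))
  context <- match.arg(context, c("CG", "CHG", "CHH"))
  cls <- classify_code(codes, table = table)
  cls <- cls[codes$context == context]
  informative <- cls[cls != "UNINFORMATIVE"]
  n <- length(informative)
  if (n == 0L)
    stop("no informative sites in context ", context, call. = FALSE)
  n_sv  <- sum(informative == "SV")
  n_inc <- sum(informative == "INCONSISTENT")
  if (inconsistent_as_sv) n_sv <- n_sv + n_inc
  sv   <- 100 * n_sv / n
  dmv  <- 100 * sum(informative == "DMV") / n
  dnmv <- 100 * sum(informative == "DNMV") / n
  out <- data.frame(
    context = context, sv_pct = sv, dmv_pct = dmv, dnmv_pct = dnmv,
    tciv_pct = sv + dmv + dnmv, n_informative = n, n_inconsistent = n_inc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variation_profile", class(out))
  out
}

#' Read a zero-one metAFLP marker table
#'
#' Expects delimited text with one row per locus and platform: columns
#' `locus_id`, `platform` (`ACC` = Acc65I/MseI, `KPN` = KpnI/MseI),
#' `primer_extension`, followed by one 0/1 column per individual. By
#' convention the first individual column is the donor.
#'
#' @param path file path.
#' @param sep field separator (default tab; `","` for CSV).
#' @return A validated `marker_table` data frame.
#' @export
read_marker_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_marker_table(tab)
}

#' Validate a data frame as a metAFLP marker table
#'
#' @param tab data frame with columns `locus_id`, `platform`,
#'   `primer_extension` and one 0/1 column per individual.
#' @return The input with class `marker_table` prepended.
#' @export
as_marker_table <- function(tab) {
  need <- c("locus_id", "platform", "primer_extension")
  if (!all(need %in% names(tab)))
    stop("marker table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$platform %in% c("ACC", "KPN")))
    stop("platform must be ACC or KPN", call. = FALSE)
  ind <- setdiff(names(tab), need)
  if (length(ind) < 2L)
    stop("need at least a donor and one regenerant column", call. = FALSE)
  vals <- as.matrix(tab[ind])
  if (!all(vals %in% c(0L, 1L)))
    stop("individual columns must be 0/1", call. = FALSE)
  if (any(nchar(tab$primer_extension) == 0) ||
      any(grepl("[^ACGT]", toupper(tab$primer_extension))))
    stop("primer_extension must be non-empty over {A,C,G,T}", call. = FALSE)
  if (!inherits(tab, "marker_table")) class(tab) <- c("marker_table", class(tab))
  tab
}

#' Merge technical replicate columns of a marker table
#'
#' metAFLP protocols often run two samples per plant; replicate band columns
#' are merged into one column per plant before coding.
#'
#' @param tab a `marker_table`.
#' @param groups named list mapping each output individual name to the
#'   replicate column names to merge.
#' @param rule `"or"` (band present in any replicate, default) or `"and"`
#'   (present in all replicates).
#' @return A `marker_table` with one column per group.
#' @export
merge_replicates <- function(tab, groups, rule = c("or", "and")) {
  rule <- match.arg(rule)
  tab <- as_marker_table(tab)
  meta <- tab[c("locus_id", "platform", "primer_extension")]
  f <- if (rule == "or") function(m) as.integer(rowSums(m) > 0)
       else function(m) as.integer(rowSums(m) == ncol(m))
  merged <- lapply(groups, function(cols) {
    if (!all(cols %in% names(tab)))
      stop("unknown replicate column(s): ",
           paste(setdiff(cols, names(tab)), collapse = ", "), call. = FALSE)
    f(as.matrix(tab[cols]))
  })
  as_marker_table(cbind(meta, as.data.frame(merged)))
}

#' Per-context variation profiles for one donor/regenerant pair
#'
#' Juxtaposes the donor and one regenerant band profile across both enzyme
#' platforms, forms the 4-digit code per locus, classifies it, and summarizes
#' SV/DMV/DNMV/TCIV percentages per methylation context. Loci present on only
#' one platform, or with an unclassifiable primer extension, are excluded and
#' reported in the QC attribute.
#'
#' @param tab a `marker_table` (both platforms for every locus).
#' @param regenerant name of the regenerant's 0/1 column.
#' @param donor name of the donor column; defaults to the first individual
#'   column.
#' @param inconsistent_as_sv see [quantify_variation()].
#' @param table classification table.
#' @return A `variation_profile` data frame with one row per context present,
#'   with attribute `qc`: a list with `excluded_loci` (missing a platform),
#'   `unassigned_loci` (no context) and `n_inconsistent` per context.
#' @export
profile_regenerant <- function(tab, regenerant, donor = NULL,
                               inconsistent_as_sv = FALSE,
                               table = metaflp_truth_table()) {
  tab <- as_marker_table(tab)
  ind <- setdiff(names(tab), c("locus_id", "platform", "primer_extension"))
  if (is.null(donor)) donor <- ind[1]
  if (!all(c(donor, regenerant) %in% ind))
    stop("donor/regenerant column not found", call. = FALSE)
  acc <- tab[tab$platform == "ACC", ]
  kpn <- tab[tab$platform == "KPN", ]
  common <- intersect(acc$locus_id, kpn$locus_id)
  excluded <- setdiff(unique(tab$locus_id), common)
  if (length(excluded))
    warning(length(excluded), " locus/loci present on one platform only; excluded",
            call. = FALSE)
  acc <- acc[match(common, acc$locus_id), ]
  kpn <- kpn[match(common, kpn$locus_id), ]
  ctx <- suppressWarnings(
    assign_context(acc$primer_extension, on_unmatched = "na"))
  unassigned <- common[is.na(ctx)]
  keep <- !is.na(ctx)
  codes <- encode_site(acc[[donor]][keep], acc[[regenerant]][keep],
                       kpn[[donor]][keep], kpn[[regenerant]][keep],
                       as.character(ctx[keep]))
  present <- intersect(c("CG", "CHG", "CHH"), unique(as.character(codes$context)))
  prof <- do.call(rbind, lapply(present, function(cc)
    quantify_variation(codes, cc, inconsistent_as_sv = inconsistent_as_sv,
                       table = table)))
  rownames(prof) <- NULL
  attr(prof, "qc") <- list(
    excluded_loci = excluded,
    unassigned_loci = unassigned,
    n_inconsistent = stats::setNames(prof$n_inconsistent, prof$context)
  )
  prof
}
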