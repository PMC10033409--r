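#' Construct an interface alignment
#'
#' Rows are receptors, columns are G-protein-binding interface positions; the
#' `group` map records each receptor's primary transducer family, since
#' conservation is computed within each primary-coupling group separately.
#'
#' @param residues Character matrix (receptors x positions) of one-letter
#'   amino acids, `"-"` for a gap. Row names are receptor ids.
#' @param group Named character vector mapping receptor_id -> primary family.
#' @param positions Optional character vector of interface-position labels.
#' @return An object of class `interface_alignment`.
#' @export
interface_alignment <- function(residues, group, positions = colnames(residues)) {
  stopifnot(is.matrix(residues), !is.null(rownames(residues)))
  ids <- rownames(residues)
  if (!all(ids %in% names(group))) stop("every receptor needs a group assignment")
  if (is.null(positions)) positions <- paste0("p", seq_len(ncol(residues)))
  structure(list(receptor_ids = ids, positions = positions,
                 residues = residues, group = group[ids]),
            class = "interface_alignment")
}

# BLOSUM62 similarity normalized to [0, 1] over the 20 standard amino acids:
# s(a, b) = (M[a,b] - min M) / (min(M[a,a], M[b,b]) - min M), so that
# self-similarity is exactly 1 and off-diagonal pairs stay below it; gap
# involvement contributes 0 under gaps = "count".
.blosum62_norm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
      m <- e$BLOSUM62[aa, aa]
      lo <- min(m)
      dmin <- outer(diag(m), diag(m), pmin)
      cache <<- pmin((m - lo) / (dmin - lo), 1)
    }
    cache
  }
})

.residue_similarity <- function(a, b, method, mat) {
  if (method == "identity") return(as.numeric(a == b))
  out <- numeric(length(a))
  ok <- a %in% rownames(mat) & b %in% rownames(mat)
  out[ok] <- mat[cbind(a[ok], b[ok])]
  out
}

#' Per-receptor G protein interface conservation
#'
#' For each receptor, the score is the mean over interface positions of the
#' mean pairwise residue similarity between that receptor and all other
#' members of its primary-coupling group at that position, with similarity
#' normalized to \[0, 1\] (diagonal-normalized BLOSUM62 by default, so
#' self-similarity is exactly 1, or strict identity). Gap-residue and gap-gap
#' pairs score 0 and are counted by
#' default; `gaps = "exclude"` drops them from the position means instead.
#' Receptors in singleton groups get `NA` with `flag = "singleton_group"`.
#'
#' @param aln An [interface_alignment()].
#' @param similarity `"blosum62"` (default) or `"identity"`.
#' @param gaps `"count"` (default) or `"exclude"`.
#' @return data.frame: receptor_id, group, score, flag.
#' @export
interface_conservation <- function(aln, similarity = c("blosum62", "identity"),
                                   gaps = c("count", "exclude")) {
  stopifnot(inherits(aln, "interface_alignment"))
  similarity <- match.arg(similarity)
  gaps <- match.arg(gaps)
  res <- aln$residues
  if (!nrow(res) || !ncol(res)) stop("input error: empty alignment")
  mat <- if (similarity == "blosum62") .blosum62_norm() else NULL
  ids <- aln$receptor_ids
  scores <- rep(NA_real_, length(ids))
  flags <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    members <- which(aln$group == aln$group[i])
    others <- setdiff(members, i)
    if (!length(others)) {
      flags[i] <- "singleton_group"
      next
    }
    pos_means <- vapply(seq_len(ncol(res)), function(j) {
      a <- rep(res[i, j], length(others))
      b <- res[others, j]
      gap_pair <- a == "-" | b == "-"
      s <- .residue_similarity(a, b, similarity, mat)
      s[gap_pair] <- 0
      if (gaps == "exclude") {
        if (all(gap_pair)) return(NA_real_)
        s <- s[!gap_pair]
      }
      mean(s)
    }, numeric(1))
    scores[i] <- mean(pos_means, na.rm = TRUE)
  }
  data.frame(receptor_id = ids, group = unname(aln$group),
             score = scores, flag = flags, stringsAsFactors = FALSE)
}

#' Classify receptors into the short/long ICL3 selectivity regimes
#'
#' Receptors separate into two selectivity regimes demarcated by ICL3 length:
#' short loops (selectivity carried by the G protein interface) and long loops
#' (coupling gated by ICL3). Lengths at or above the threshold (46 residues by
#' default) fall in the long, ICL3-gated regime.
#'
#' @param icl3_length Non-negative integer length(s); vectorized.
#' @param threshold Demarcation length in residues (default 46).
#' @return Character vector: `"interface_specificity"` (short) or
#'   `"gated_by_ICL3"` (long).
#' @export
classify_regime <- function(icl3_length, threshold = 46L) {
  if (any(icl3_length < 0)) stop("input error: negative ICL3 length")
  ifelse(icl3_length >= threshold, "gated_by_ICL3", "interface_specificity")
}

#' G protein coupling overlap per ICL3-length regime
#'
#' Tallies, within each regime, how many receptors occupy each Venn region of
#' the Gs/Gq/Gi coupling diagram, plus a promiscuity index: the fraction of
#' receptors coupling to two or more of the three families. Receptors with an
#' empty coupling set are excluded with a warning.
#'
#' @param panel List of [receptor_record()]s (each needs a non-empty
#'   `coupling` set and an ICL3 length derivable via [extract_icl3()]), or a
#'   data.frame with columns `receptor_id`, `icl3_length`, `coupling`
#'   (slash-separated).
#' @param threshold Passed to [classify_regime()].
#' @return Named list of per-regime summaries, each with `regime`, `n`,
#'   `overlap_counts` (named vector over non-empty subsets of Gs/Gq/Gi) and
#'   `promiscuity_index`.
#' @export
coupling_overlap <- function(panel, threshold = 46L) {
  if (is.data.frame(panel)) {
    lens <- panel$icl3_length
    coups <- strsplit(panel$coupling, "/")
    ids <- panel$receptor_id
  } else {
    segs <- lapply(panel, extract_icl3)
    lens <- vapply(segs, `[[`, integer(1), "length")
    coups <- lapply(panel, `[[`, "coupling")
    ids <- vapply(panel, `[[`, character(1), "receptor_id")
  }
  fams <- c("Gs", "Gq", "Gi")
  coups <- lapply(coups, function(v) intersect(fams, v))
  empty <- lengths(coups) == 0L
  if (any(empty)) {
    warning(sum(empty), " receptor(s) with empty coupling set excluded")
    lens <- lens[!empty]; coups <- coups[!empty]; ids <- ids[!empty]
  }
  regime <- classify_regime(lens, threshold)
  regions <- unlist(lapply(seq_along(fams), function(k)
    utils::combn(fams, k, paste, collapse = "&", simplify = TRUE)))
  out <- list()
  for (rg in c("interface_specificity", "gated_by_ICL3")) {
    sel <- regime == rg
    labels <- vapply(coups[sel], paste, character(1), collapse = "&")
    counts <- stats::setNames(integer(length(regions)), regions)
    tab <- table(labels)
    counts[names(tab)] <- as.integer(tab)
    out[[rg]] <- list(regime = rg, n = sum(sel), overlap_counts = counts,
                      promiscuity_index = if (sum(sel)) mean(lengths(coups[sel]) >= 2L) else NA_real_)
  }
  out
}

#' Cognate versus secondary G protein coupling gap
#'
#' For each receptor with quantitative coupling values for two or more
#' transducer families, the family with the highest log(Emax/EC50) is the
#' cognate pathway and the second-highest the secondary; the gap is their
#' difference (always >= 0). Receptors with a value for only a single family
#' are excluded. Ties are broken by the fixed family order Gs > Gi > Gq > G12.
#'
#' @param profiles data.frame with columns `receptor_id`, `family`, `value`
#'   (log10(Emax/EC50)).
#' @return data.frame: receptor_id, cognate_family, cognate_value,
#'   secondary_family, secondary_value, gap.
#' @export
cognate_secondary_gap <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("receptor_id", "family", "value") %in% names(profiles)))
  if (!nrow(profiles)) stop("input error: empty coupling profiles")
  fam_order <- c("Gs", "Gi", "Gq", "G12")
  rows <- lapply(split(profiles, profiles$receptor_id), function(d) {
    if (nrow(d) < 2L) return(NULL)  # single-family receptors are excluded
    ord <- order(-d$value, match(d$family, fam_order))
    d <- d[ord, ]
    data.frame(receptor_id = d$receptor_id[1],
               cognate_family = d$family[1], cognate_value = d$value[1],
               secondary_family = d$family[2], secondary_value = d$value[2],
               gap = d$value[1] - d$value[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(receptor_id = character(), cognate_family = character(),
                      cognate_value = numeric(), secondary_family = character(),
                      secondary_value = numeric(), gap = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Contrast interface-conservation distributions between regimes
#'
#' Descriptive comparison (no hypothesis test): per-regime mean, standard
#' deviation and interquartile range of the conservation scores, the mean
#' difference (short minus long) and the IQR spread ratio (short / long).
#' A regime with fewer than two scored receptors is flagged degenerate.
#'
#' @param scores Numeric conservation scores.
#' @param regimes Character regime labels, parallel to `scores`.
#' @return List with `per_regime` data.frame, `mean_difference`,
#'   `spread_ratio`, `degenerate` flag.
#' @export
regime_contrast <- function(scores, regimes) {
  stopifnot(length(scores) == length(regimes))
  ok <- !is.na(scores)
  scores <- scores[ok]; regimes <- regimes[ok]
  lv <- c("interface_specificity", "gated_by_ICL3")
  per <- do.call(rbind, lapply(lv, function(rg) {
    v <- scores[regimes == rg]
    data.frame(regime = rg, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               iqr = if (length(v) > 1) stats::IQR(v) else NA_real_)
  }))
  degenerate <- any(per$n < 2L)
  list(per_regime = per,
       mean_difference = per$mean[1] - per$mean[2],
       spread_ratio = per$iqr[1] / per$iqr[2],
       degenerate = degenerate)
}

#' Read an interface alignment from a TSV matrix
#'
#' @param file TSV with a `receptor_id` column, a `group` column, and one
#'   column per interface position containing one-letter residues.
#' @return An [interface_alignment()].
#' @export
read_interface_alignment <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("receptor_id", "group") %in% names(df)))
  pos_cols <- setdiff(names(df), c("receptor_id", "group"))
  res <- as.matrix(df[, pos_cols, drop = FALSE])
  rownames(res) <- df$receptor_id
  interface_alignment(res, stats::setNames(df$group, df$receptor_id), pos_cols)
}
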