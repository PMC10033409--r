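#' Construct a receptor record
#'
#' A receptor record bundles a protein sequence with 1-based inclusive
#' structural-segment annotations (TM5, TM6, ICL1..ICL3, ...) and an optional
#' set of transducer (G protein) families the receptor couples to.
#'
#' @param receptor_id Character scalar identifier.
#' @param sequence Amino-acid string; positions are 1-based.
#' @param segments Named list of length-2 integer vectors `c(start, end)`,
#'   inclusive, named by element label (`"TM5"`, `"ICL3"`, ...).
#' @param coupling Character vector of transducer families, subset of
#'   `c("Gs", "Gi", "Gq", "G12")`. May be empty if the record is not used by
#'   selectivity analyses.
#' @param receptor_class Character scalar (e.g. `"classA"`); optional.
#'
#' @return An object of class `receptor_record`.
#' @export
receptor_record <- function(receptor_id, sequence, segments = list(),
                            coupling = character(), receptor_class = NA_character_) {
  stopifnot(is.character(receptor_id), length(receptor_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  fams <- c("Gs", "Gi", "Gq", "G12")
  if (length(coupling) && !all(coupling %in% fams)) {
    stop("coupling families must be among: ", paste(fams, collapse = ", "))
  }
  for (lab in names(segments)) {
    iv <- segments[[lab]]
    if (length(iv) != 2L || anyNA(iv)) stop("segment '", lab, "' must be c(start, end)")
    if (iv[1] < 1L || iv[2] > n) {
      stop("segment '", lab, "' [", iv[1], ", ", iv[2], "] exceeds sequence bounds [1, ", n, "]")
    }
    # the empty-loop convention start = end + 1 is permitted
    if (iv[1] > iv[2] + 1L) stop("segment '", lab, "' has start > end + 1")
  }
  structure(list(receptor_id = receptor_id, sequence = sequence,
                 segments = segments, coupling = unique(coupling),
                 receptor_class = receptor_class),
            class = "receptor_record")
}

#' @export
print.receptor_record <- function(x, ...) {
  cat("<receptor_record>", x$receptor_id, "-", nchar(x$sequence), "aa,",
      length(x$segments), "segments")
  if (length(x$coupling)) cat(", couples:", paste(x$coupling, collapse = "/"))
  cat("\n")
  invisible(x)
}

#' Extract the third intracellular loop from a receptor record
#'
#' Uses the explicit `ICL3` annotation when present; otherwise infers the loop
#' as the gap between the cytosolic end of TM5 and the start of TM6 (first
#' residue after TM5 through last residue before TM6). Adjacent helices give
#' the empty segment (length 0, `start = end + 1` convention).
#'
#' @param receptor A [receptor_record()].
#' @return A list of class `icl3_segment` with fields `receptor_id`, `start`,
#'   `end`, `subsequence`, `length`.
#' @export
#' @examples
#' r <- receptor_record("b2ar-like", strrep("A", 300),
#'                      segments = list(ICL3 = c(236L, 257L)))
#' extract_icl3(r)$length  # 22
extract_icl3 <- function(receptor) {
  stopifnot(inherits(receptor, "receptor_record"))
  segs <- receptor$segments
  if (!is.null(segs$ICL3)) {
    iv <- segs$ICL3
  } else if (!is.null(segs$TM5) && !is.null(segs$TM6)) {
    iv <- c(segs$TM5[2] + 1L, segs$TM6[1] - 1L)
  } else {
    stop("annotation error: record '", receptor$receptor_id,
         "' carries neither an ICL3 interval nor TM5/TM6 intervals")
  }
  n <- nchar(receptor$sequence)
  len <- iv[2] - iv[1] + 1L
  if (len < 0L) stop("bounds error: inferred ICL3 interval has negative width")
  if (len > 0L && (iv[1] < 1L || iv[2] > n)) {
    stop("bounds error: ICL3 interval [", iv[1], ", ", iv[2],
         "] exceeds sequence bounds [1, ", n, "]")
  }
  sub <- if (len > 0L) substr(receptor$sequence, iv[1], iv[2]) else ""
  structure(list(receptor_id = receptor$receptor_id,
                 start = as.integer(iv[1]), end = as.integer(iv[2]),
                 subsequence = sub, length = as.integer(len)),
            class = "icl3_segment")
}

#' Map an ICL3-relative position to the N/C loop coordinate scheme
#'
#' ICL3 varies widely in length across receptors, so positions are tracked
#' from both ends: the N-terminal half is numbered N1..Nn outward from TM5 and
#' the C-terminal half Cn..C1 inward toward TM6, with n half the loop length.
#' For odd lengths the middle position is assigned to the N side.
#'
#' @param position 1-based position within the loop.
#' @param icl3_length Loop length (>= 1).
#' @return A list of class `loop_coordinate` with fields `side` ("N" or "C")
#'   and `rank` (>= 1).
#' @seealso [nc_to_position()] for the inverse map.
#' @export
map_to_nc_coordinate <- function(position, icl3_length) {
  stopifnot(icl3_length >= 1L)
  if (position < 1L || position > icl3_length) {
    stop("range error: position ", position, " outside [1, ", icl3_length, "]")
  }
  n_half <- ceiling(icl3_length / 2)
  if (position <= n_half) {
    out <- list(side = "N", rank = as.integer(position))
  } else {
    out <- list(side = "C", rank = as.integer(icl3_length - position + 1L))
  }
  structure(out, class = "loop_coordinate")
}

#' Invert an N/C loop coordinate back to a loop position
#'
#' @param coord A `loop_coordinate` (or list with `side` and `rank`).
#' @param icl3_length Host loop length.
#' @return 1-based integer position.
#' @export
nc_to_position <- function(coord, icl3_length) {
  stopifnot(coord$side %in% c("N", "C"), coord$rank >= 1L)
  pos <- if (coord$side == "N") coord$rank else icl3_length - coord$rank + 1L
  if (pos < 1L || pos > icl3_length) stop("coordinate outside host loop")
  # reject coordinates on the wrong side of the midline
  chk <- map_to_nc_coordinate(pos, icl3_length)
  if (chk$side != coord$side || chk$rank != coord$rank) {
    stop("coordinate ", coord$side, coord$rank,
         " is not valid for a loop of length ", icl3_length)
  }
  as.integer(pos)
}

round_half_up <- function(x) floor(x + 0.5)

#' Rescale a loop position onto a normalized length frame
#'
#' Loops of different lengths are compared by normalizing every position onto
#' the shortest loop in the dataset (22 residues by default): a linear map of
#' bin centres, rounded half-up and clamped to the target frame. The map is
#' monotone non-decreasing and sends endpoints to endpoints.
#'
#' @param position 1-based source position (vectorized).
#' @param source_length Length of the host loop.
#' @param target_length Normalization length (default 22).
#' @return Integer position(s) on the target scale.
#' @export
rescale_position <- function(position, source_length, target_length = 22L) {
  stopifnot(source_length >= 1L, target_length >= 1L)
  if (target_length > source_length) {
    stop("scaling error: target_length (", target_length,
         ") exceeds source_length (", source_length, ")")
  }
  if (any(position < 1L | position > source_length)) {
    stop("range error: position outside [1, ", source_length, "]")
  }
  p <- round_half_up((position - 0.5) * target_length / source_length + 0.5)
  as.integer(pmin(pmax(p, 1L), target_length))
}

#' Normalize a loop coordinate onto the target frame
#'
#' Rescales the underlying position while preserving the side/rank reading of
#' the coordinate on the target frame.
#'
#' @inheritParams nc_to_position
#' @inheritParams rescale_position
#' @return A `loop_coordinate` on the target frame.
#' @export
normalize_coordinate <- function(coord, source_length, target_length = 22L) {
  pos <- nc_to_position(coord, source_length)
  map_to_nc_coordinate(rescale_position(pos, source_length, target_length),
                       target_length)
}

#' Construct a mutation record
#'
#' One literature observation of an ICL3 mutation's functional effect, on one
#' of the three metrics collected for the meta-analysis (agonist pKd, pEC50,
#' Emax), with loop-relative 1-based positions of the mutated residues.
#'
#' @param receptor_id Host receptor identifier.
#' @param positions Integer vector of ICL3-relative positions (>= 1 element).
#' @param mutation_kind One of `"substitution"`, `"deletion"`, `"chimera"`.
#' @param metric One of `"pKd_agonist"`, `"pEC50"`, `"Emax"`.
#' @param wt_value,mut_value Wild-type and mutant values on the metric scale.
#' @return A list of class `mutation_record`; `delta = mut_value - wt_value`.
#' @export
mutation_record <- function(receptor_id, positions, mutation_kind, metric,
                            wt_value, mut_value) {
  mutation_kind <- match.arg(mutation_kind, c("substitution", "deletion", "chimera"))
  metric <- match.arg(metric, c("pKd_agonist", "pEC50", "Emax"))
  positions <- as.integer(positions)
  if (!length(positions) || any(positions < 1L)) {
    stop("positions must be a non-empty vector of 1-based loop positions")
  }
  structure(list(receptor_id = receptor_id, positions = positions,
                 mutation_kind = mutation_kind, metric = metric,
                 wt_value = wt_value, mut_value = mut_value,
                 delta = mut_value - wt_value),
            class = "mutation_record")
}

#' Aggregate mutation effects onto normalized loop positions
#'
#' Each mutated position is assigned the effect (delta = mutant - wild type)
#' of its mutation; a multi-position mutant contributes its delta to every
#' mutated position. Positions are rescaled onto the normalization frame and
#' effects are aggregated separately per metric. Chimera/insertion records are
#' excluded by default since their positions do not map onto the host frame.
#'
#' @param records List of [mutation_record()]s.
#' @param icl3_lengths Named integer vector, host ICL3 length per receptor_id.
#' @param normalize_to Normalization frame length (default 22).
#' @param include_chimera Include `mutation_kind == "chimera"` records?
#' @return List with `assignments` (data.frame: receptor_id, metric,
#'   source_position, position, delta — one row per mutated position) and
#'   `summary` (data.frame: position, metric, n, mean_delta).
#' @export
aggregate_mutation_effects <- function(records, icl3_lengths,
                                       normalize_to = 22L,
                                       include_chimera = FALSE) {
  stopifnot(is.list(records))
  rows <- list()
  for (rec in records) {
    stopifnot(inherits(rec, "mutation_record"))
    if (rec$mutation_kind == "chimera" && !include_chimera) next
    L <- if (rec$receptor_id %in% names(icl3_lengths))
      icl3_lengths[[rec$receptor_id]] else NULL
    if (is.null(L) || is.na(L)) {
      stop("lookup error: unknown ICL3 length for receptor '", rec$receptor_id, "'")
    }
    if (any(rec$positions > L)) {
      stop("record positions exceed host ICL3 length for '", rec$receptor_id, "'")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      receptor_id = rec$receptor_id, metric = rec$metric,
      source_position = rec$positions,
      position = rescale_position(rec$positions, L, normalize_to),
      delta = rec$delta, stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(receptor_id = character(), metric = character(),
               source_position = integer(), position = integer(),
               delta = numeric())
  if (nrow(assignments)) {
    agg <- aggregate(delta ~ position + metric, data = assignments,
                     FUN = function(v) c(n = length(v), mean = mean(v)))
    summary_df <- data.frame(position = agg$position, metric = agg$metric,
                             n = as.integer(agg$delta[, "n"]),
                             mean_delta = agg$delta[, "mean"])
    summary_df <- summary_df[order(summary_df$metric, summary_df$position), ]
    rownames(summary_df) <- NULL
  } else {
    summary_df <- data.frame(position = integer(), metric = character(),
                             n = integer(), mean_delta = numeric())
  }
  list(assignments = assignments, summary = summary_df)
}

#' Read a receptor panel from FASTA + annotation TSV
#'
#' @param fasta_file FASTA of receptor sequences (names = receptor ids).
#' @param annot_file Tab-separated annotation table with columns
#'   `receptor_id`, `element`, `start`, `end` and optionally `coupling`
#'   (slash-separated families) and `class`.
#' @return Named list of [receptor_record()]s.
#' @export
read_receptor_panel <- function(fasta_file, annot_file) {
  seqs <- Biostrings::readAAStringSet(fasta_file)
  ids <- sub("\\s.*$", "", names(seqs))
  annot <- utils::read.delim(annot_file, stringsAsFactors = FALSE)
  need <- c("receptor_id", "element", "start", "end")
  if (!all(need %in% names(annot))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (i in seq_along(seqs)) {
    id <- ids[i]
    rows <- annot[annot$receptor_id == id, , drop = FALSE]
    segs <- lapply(seq_len(nrow(rows)), function(j) c(rows$start[j], rows$end[j]))
    names(segs) <- rows$element
    coup <- character()
    if ("coupling" %in% names(rows) && nrow(rows)) {
      coup <- unique(unlist(strsplit(rows$coupling[!is.na(rows$coupling)], "/")))
      coup <- coup[nzchar(coup)]
    }
    cls <- if ("class" %in% names(rows) && nrow(rows)) rows$class[1] else NA_character_
    out[[id]] <- receptor_record(id, as.character(seqs[[i]]), segs, coup, cls)
  }
  out
}

#' Write extracted ICL3 segments to a TSV
#'
#' @param panel Named list of [receptor_record()]s.
#' @param file Output path.
#' @return The segment data.frame, invisibly.
#' @export
write_icl3_segments <- function(panel, file) {
  segs <- lapply(panel, extract_icl3)
  df <- data.frame(receptor_id = vapply(segs, `[[`, character(1), "receptor_id"),
                   start = vapply(segs, `[[`, integer(1), "start"),
                   end = vapply(segs, `[[`, integer(1), "end"),
                   length = vapply(segs, `[[`, integer(1), "length"),
                   subsequence = vapply(segs, `[[`, character(1), "subsequence"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
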