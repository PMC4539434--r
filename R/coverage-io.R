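#' @title Per-base coverage input, normalization and position rescaling
#' @name coverage-io
#' @description Readers for per-base read-count profiles (long TSV or
#'   bedGraph), count normalization to log expression, and affine mapping
#'   of genomic coordinates onto the canonical \code{[0, 100]} scale.
NULL

new_coverage_profile <- function(gene_id, sample_id, positions, counts,
                                 group = NA_character_) {
  positions <- as.numeric(positions)
  counts <- as.numeric(counts)
  if (length(positions) != length(counts))
    stop("positions and counts must have equal length")
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(counts < 0))
    stop("counts must be non-negative")
  structure(list(gene_id = as.character(gene_id),
                 sample_id = as.character(sample_id),
                 group = group,
                 positions = positions, counts = counts),
            class = "coverage_profile")
}

#' Construct an expression curve
#'
#' Validated container for one sample's normalized log-expression values
#' \code{y} at rescaled positions \code{t} (at least 4 positions, finite
#' values).
#'
#' @param gene_id,sample_id identifiers.
#' @param t numeric positions (canonically in \code{[0, 100]}).
#' @param y numeric expression values, same length as \code{t}.
#' @param group optional group label.
#' @return an object of class \code{"expression_curve"}.
#' @export
expression_curve <- function(gene_id, sample_id, t, y,
                             group = NA_character_) {
  new_expression_curve(gene_id, sample_id, t, y, group)
}

new_expression_curve <- function(gene_id, sample_id, t, y,
                                 group = NA_character_) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) < 4) stop("an expression curve needs at least 4 positions")
  if (!all(is.finite(y))) stop("y must be finite")
  structure(list(gene_id = as.character(gene_id),
                 sample_id = as.character(sample_id),
                 group = group, t = t, y = y),
            class = "expression_curve")
}

#' @export
print.expression_curve <- function(x, ...) {
  cat(sprintf("expression_curve %s/%s%s: %d positions on [%g, %g], y in [%.3g, %.3g]\n",
              x$gene_id, x$sample_id,
              if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              length(x$t), min(x$t), max(x$t), min(x$y), max(x$y)))
  invisible(x)
}

#' Read per-base coverage profiles
#'
#' Accepts either a long TSV with header columns
#' \code{gene_id, sample_id, position, count} (positions 1-based
#' inclusive) or a headerless 4-column bedGraph
#' (\code{chrom, start, end, count}; 0-based half-open intervals, expanded
#' here to per-base 1-based positions).  A bedGraph file carries no sample
#' column, so \code{sample_id} names the sample (default: file basename).
#'
#' @param path coverage file.
#' @param labels_path optional TSV with header \code{sample_id, group};
#'   when given, every sample in the coverage file must appear in it.
#' @param format \code{"auto"} (default), \code{"tsv"} or
#'   \code{"bedgraph"}.
#' @param sample_id sample name used for bedGraph input.
#' @return list of \code{coverage_profile} objects, one per
#'   (gene, sample), positions sorted.
#' @export
read_coverage <- function(path, labels_path = NULL, format = "auto",
                          sample_id = NULL) {
  format <- match.arg(format, c("auto", "tsv", "bedgraph"))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(list())
  if (format == "auto") {
    f1 <- strsplit(first, "[\t ]+")[[1]]
    format <- if (length(f1) >= 4 && identical(tolower(f1[1]), "gene_id"))
      "tsv" else "bedgraph"
  }
  if (format == "tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("gene_id", "sample_id", "position", "count")
    if (!all(need %in% names(d)))
      stop("long TSV coverage needs columns: ", paste(need, collapse = ", "))
  } else {
    d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "count"))
    if (is.null(sample_id))
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    # bedGraph: 0-based half-open [start, end) -> 1-based inclusive bases
    reps <- d$end - d$start
    if (any(reps <= 0)) {
      bad <- which(reps <= 0)[1]
      stop("bedGraph interval with end <= start at line ", bad, ": ",
           paste(d[bad, ], collapse = "\t"))
    }
    d <- data.frame(
      gene_id = rep(d$chrom, reps),
      sample_id = sample_id,
      position = unlist(lapply(seq_len(nrow(d)),
                               function(i) (d$start[i] + 1L):d$end[i])),
      count = rep(d$count, reps),
      stringsAsFactors = FALSE)
  }
  if (any(d$count < 0)) {
    bad <- which(d$count < 0)[1]
    stop("negative count at row ", bad, ": ",
         paste(unlist(d[bad, ]), collapse = "\t"))
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(labels)))
      stop("labels file needs columns sample_id, group")
    unknown <- setdiff(unique(d$sample_id), labels$sample_id)
    if (length(unknown))
      stop("sample_id not present in labels file: ",
           paste(unknown, collapse = ", "))
  }
  key <- interaction(d$gene_id, d$sample_id, drop = TRUE, sep = "\r")
  lapply(split(d, key), function(g) {
    o <- order(g$position)
    g <- g[o, ]
    if (anyDuplicated(g$position)) {
      bad <- g$position[duplicated(g$position)][1]
      stop("duplicate (gene, sample, position): ", g$gene_id[1], ", ",
           g$sample_id[1], ", position ", bad)
    }
    grp <- if (is.null(labels)) NA_character_ else
      labels$group[match(g$sample_id[1], labels$sample_id)]
    new_coverage_profile(g$gene_id[1], g$sample_id[1],
                         g$position, g$count, group = grp)
  })
}

#' Affine rescaling of genomic coordinates to [0, 100]
#'
#' @param positions numeric coordinates in \code{[a, b]}.
#' @param a,b gene interval endpoints, \code{b > a}.
#' @return \code{100 * (positions - a) / (b - a)}.
#' @export
rescale_positions <- function(positions, a, b) {
  if (!is.finite(a) || !is.finite(b) || b <= a)
    stop("gene interval must satisfy b > a")
  if (length(positions) && (min(positions) < a || max(positions) > b))
    stop("positions fall outside the gene interval [", a, ", ", b, "]")
  100 * (positions - a) / (b - a)
}

#' Normalize a coverage profile to a log-expression curve
#'
#' Counts are divided by a per-sample scale factor, incremented by 1, and
#' natural-log transformed, so bases with zero coverage map to exactly 0.
#' Positions are mapped onto \code{[0, 100]}.  When an explicit gene
#' \code{interval} is supplied, bases of the interval without a record are
#' filled in as zero counts; otherwise only observed positions are used
#' and the observed span defines the rescaling.
#'
#' @param profile a \code{coverage_profile}.
#' @param scale_factor positive per-sample normalization factor (see
#'   \code{\link{compute_scale_factors}}).
#' @param interval optional length-2 gene interval \code{c(a, b)}
#'   (1-based inclusive coordinates).
#' @return an \code{expression_curve} with \code{t} in \code{[0, 100]} and
#'   \code{y = log(count / scale_factor + 1)}.
#' @export
normalize <- function(profile, scale_factor, interval = NULL) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (!is.finite(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be a positive number")
  pos <- profile$positions; cnt <- profile$counts
  if (!is.null(interval)) {
    a <- interval[1]; b <- interval[2]
    if (b <= a) stop("gene interval must satisfy b > a")
    full <- seq(a, b)
    cnt_full <- numeric(length(full))
    cnt_full[match(pos, full)] <- cnt
    pos <- full; cnt <- cnt_full
  } else {
    a <- pos[1]; b <- pos[length(pos)]
  }
  y <- log1p(cnt / scale_factor)
  new_expression_curve(profile$gene_id, profile$sample_id,
                       t = rescale_positions(pos, a, b), y = y,
                       group = profile$group)
}

#' Per-sample scale factors from total mapped reads
#'
#' Default normalization: each sample's total count divided by the median
#' total across samples, so factors are O(1).
#'
#' @param profiles list of \code{coverage_profile} objects.
#' @return named numeric vector of scale factors, one per sample.
#' @export
compute_scale_factors <- function(profiles) {
  totals <- tapply(vapply(profiles, function(p) sum(p$counts), 0),
                   vapply(profiles, function(p) p$sample_id, ""), sum)
  c(totals / stats::median(totals))
}

#' Write and read expression curves as long TSV
#'
#' Floats are written with 17 significant digits, so finite doubles
#' round-trip bit-exactly.
#'
#' @param curves list of \code{expression_curve} objects.
#' @param path output/input TSV path.
#' @return \code{read_curves} returns a list of \code{expression_curve}s;
#'   \code{write_curves} returns \code{path} invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(gene_id = cv$gene_id, sample_id = cv$sample_id,
               group = cv$group, t = sprintf("%.17g", cv$t),
               y = sprintf("%.17g", cv$y), stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character",
                                        "character", "numeric", "numeric"))
  key <- interaction(d$gene_id, d$sample_id, drop = TRUE, sep = "\r")
  out <- lapply(split(d, key), function(g) {
    o <- order(g$t)
    grp <- g$group[1]
    new_expression_curve(g$gene_id[1], g$sample_id[1], g$t[o], g$y[o],
                         group = if (identical(grp, "NA")) NA_character_ else grp)
  })
  names(out) <- NULL
  out
}
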