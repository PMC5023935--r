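#' Construct a depth track
#'
#' A depth track maps 0-based half-open genomic intervals to integer read
#' depths, per chromosome. Positions absent from the track have depth 0.
#'
#' @param intervals Data.frame with columns `chrom`, `start0`, `end0`, `depth`.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(intervals) {
  stopifnot(all(c("chrom", "start0", "end0", "depth") %in% names(intervals)))
  if (any(intervals$depth < 0)) stop("negative depth in track")
  if (any(intervals$end0 <= intervals$start0)) stop("empty or inverted interval in track")
  by_chrom <- split(intervals[, c("start0", "end0", "depth")], intervals$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start0), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start0[-1L] < d$end0[-nrow(d)])) {
      stop("overlapping intervals in depth track")
    }
    rownames(d) <- NULL
    d
  })
  structure(by_chrom, class = "depth_track")
}

#' Read a per-base depth track
#'
#' Auto-detects the dialect by column count: 3 columns are samtools-depth
#' style (`chrom`, 1-based `pos`, `depth`; consecutive equal-depth positions
#' are merged into runs), 4 columns are bedGraph (`chrom`, 0-based `start`,
#' `end`, `depth`). `#` and `track` lines are skipped.
#'
#' @param path Path to the TSV/bedGraph file.
#' @return A `depth_track`.
#' @export
read_depth_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(depth_track(data.frame(
    chrom = character(0), start0 = integer(0), end0 = integer(0), depth = integer(0))))
  ncol_detected <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  con <- textConnection(lines)
  on.exit(close(con))
  if (ncol_detected == 3L) {
    df <- utils::read.table(con, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "pos", "depth"))
    if (any(df$depth < 0)) stop("negative depth in '", path, "'")
    # merge consecutive same-depth positions into runs, per chromosome
    out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
      d <- d[order(d$pos), , drop = FALSE]
      if (anyDuplicated(d$pos)) stop("duplicate positions in '", path, "'")
      brk <- c(TRUE, diff(d$pos) != 1L | diff(d$depth) != 0L)
      run <- cumsum(brk)
      data.frame(chrom = d$chrom[1L],
                 start0 = tapply(d$pos, run, min) - 1L,
                 end0 = tapply(d$pos, run, max),
                 depth = tapply(d$depth, run, `[`, 1L))
    }))
  } else if (ncol_detected == 4L) {
    df <- utils::read.table(con, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start0", "end0", "depth"))
    if (any(df$depth < 0)) stop("negative depth in '", path, "'")
    for (d in split(df, df$chrom)) {
      if (is.unsorted(d$start0)) stop("unsorted bedGraph intervals in '", path, "'")
    }
    out <- df
  } else {
    stop("unrecognized depth-track dialect in '", path, "' (", ncol_detected, " columns)")
  }
  depth_track(out)
}

#' Write a depth track as bedGraph
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  chroms <- sort(names(track))
  lines <- unlist(lapply(chroms, function(ch) {
    d <- track[[ch]]
    paste(ch, d$start0, d$end0, d$depth, sep = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Depth at a single base
#'
#' @param track A `depth_track`.
#' @param chrom Chromosome.
#' @param pos 1-based position(s).
#' @return Integer depth(s); 0 for positions absent from the track.
#' @export
position_depth <- function(track, chrom, pos) {
  d <- track[[chrom]]
  if (is.null(d) || nrow(d) == 0L) return(rep(0L, length(pos)))
  p0 <- as.integer(pos) - 1L
  i <- findInterval(p0, d$start0)
  out <- integer(length(p0))
  hit <- i >= 1L
  hit[hit] <- p0[hit] < d$end0[i[hit]]
  out[hit] <- as.integer(d$depth[i[hit]])
  out
}

# bases within [start0, end0) whose depth is strictly greater than `thr`
bases_over <- function(track, chrom, start0, end0, thr) {
  d <- track[[chrom]]
  if (is.null(d) || nrow(d) == 0L) return(0L)
  keep <- d$depth > thr & d$end0 > start0 & d$start0 < end0
  if (!any(keep)) return(0L)
  d <- d[keep, , drop = FALSE]
  sum(pmin(d$end0, end0) - pmax(d$start0, start0))
}

#' Per-gene coverage fraction and exclusion flag
#'
#' Computes the fraction of the gene's coverage footprint (exon union padded
#' by `flank_pad`) with depth strictly greater than `depth_threshold`, and
#' flags the gene for exclusion when that fraction is below `min_fraction`.
#'
#' @param track A `depth_track`.
#' @param model A `gene_model`.
#' @param depth_threshold Depth that must be exceeded (default 20).
#' @param min_fraction Minimum adequately covered fraction (default 0.75).
#' @param gc_fraction Optional GC fraction to carry through to the report.
#' @return A one-row data.frame: `gene`, `footprint_bases`,
#'   `fraction_over_threshold`, `excluded`, `gc_fraction`.
#' @export
gene_coverage_fraction <- function(track, model, depth_threshold = 20L,
                                   min_fraction = 0.75, gc_fraction = NA_real_) {
  fp <- gene_footprint(model)
  total <- sum(fp$end0 - fp$start0)
  if (total <= 0L) stop("gene_model '", model$gene, "': empty footprint")
  over <- sum(vapply(seq_len(nrow(fp)), function(i) {
    bases_over(track, model$chrom, fp$start0[i], fp$end0[i], depth_threshold)
  }, integer(1L)))
  frac <- over / total
  data.frame(gene = model$gene, footprint_bases = total,
             fraction_over_threshold = frac,
             excluded = frac < min_fraction,
             gc_fraction = gc_fraction, stringsAsFactors = FALSE)
}

#' Genes failing the coverage rule
#'
#' Pure threshold filter: a gene is flagged when its fraction of footprint
#' bases above the depth threshold is strictly below `min_fraction` (the rule
#' is "less than 75%", so a fraction of exactly 0.75 is kept).
#'
#' @param stats Data.frame of per-gene coverage stats (rows as produced by
#'   [gene_coverage_fraction()]).
#' @param min_fraction Minimum adequately covered fraction (default 0.75).
#' @return Character vector of excluded gene names (unique, sorted).
#' @export
flag_low_coverage_genes <- function(stats, min_fraction = 0.75) {
  if (is.null(stats) || nrow(stats) == 0L) return(character(0))
  sort(unique(stats$gene[stats$fraction_over_threshold < min_fraction]))
}

#' Coverage exceedance summary over a region set
#'
#' Fractions of region bases with depth strictly greater than 10 and strictly
#' greater than 20, in the style of consensus-coding-sequence coverage
#' summaries.
#'
#' @param track A `depth_track`.
#' @param regions Data.frame with `chrom`, `start0`, `end0` (0-based half-open).
#' @return A list with `fraction_over_10` and `fraction_over_20`.
#' @export
coverage_summary <- function(track, regions) {
  total <- sum(regions$end0 - regions$start0)
  if (total <= 0L) stop("empty region set")
  over <- function(thr) sum(vapply(seq_len(nrow(regions)), function(i) {
    bases_over(track, regions$chrom[i], regions$start0[i], regions$end0[i], thr)
  }, integer(1L))) / total
  list(fraction_over_10 = over(10L), fraction_over_20 = over(20L))
}

#' Merge depth tracks
#'
#' Concatenates tracks covering disjoint intervals (e.g. per-chromosome or
#' per-region chunks) into one `depth_track`.
#'
#' @param ... `depth_track` objects with pairwise non-overlapping intervals.
#' @return A single `depth_track`.
#' @export
merge_depth_tracks <- function(...) {
  tracks <- list(...)
  df <- do.call(rbind, unlist(lapply(tracks, function(tr) {
    lapply(names(tr), function(ch) cbind(chrom = ch, tr[[ch]]))
  }), recursive = FALSE))
  depth_track(df)
}
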