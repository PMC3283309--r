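# Readers and writers.
#
# Mappings are accepted as SAM/BAM (via Rsamtools) or as a simple
# tab-separated paired-end ("ESP") format with one pair per line and no
# header:
#   id  chrom  leftStart  leftEnd  leftOrient  rightStart  rightEnd
#   rightOrient  quality
# Coordinates are 0-based half-open; orientation is "+" or "-". SAM/BAM
# input (1-based) is converted at this boundary.

.esp_cols <- c("id", "chrom", "left_start", "left_end", "left_orient",
               "right_start", "right_end", "right_orient", "quality")

#' Read paired-end mappings
#'
#' Reads one `PairedMapping` per properly paired record; pairs below the
#' mapping-quality threshold are dropped and counted in a message. SAM/BAM
#' records flagged secondary or supplementary are skipped (unique mapping
#' locations are assumed), unpaired records are skipped with a warning, and
#' inter-chromosomal pairs are dropped and counted.
#'
#' @param path Input file.
#' @param format One of `"esp"`, `"sam"`, `"bam"`.
#' @param min_quality Minimum mapping quality (pairs below are dropped).
#' @param source Sample label to attach (e.g. `"normal"`/`"tumor"`).
#' @return Mapping `data.frame` as from [paired_mappings()].
#' @export
read_mappings <- function(path, format = c("esp", "sam", "bam"),
                          min_quality = 20, source = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  m <- switch(format,
              esp = .read_esp(path),
              sam = .read_sam_bam(path, sam = TRUE),
              bam = .read_sam_bam(path, sam = FALSE))
  n_low <- sum(!is.na(m$quality) & m$quality < min_quality)
  if (n_low > 0) {
    message(sprintf("read_mappings: dropped %d pair(s) below quality %g",
                    n_low, min_quality))
  }
  m <- m[is.na(m$quality) | m$quality >= min_quality, , drop = FALSE]
  m$source <- rep(source, nrow(m))
  rownames(m) <- NULL
  m
}

.read_esp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty mapping file: ", path)
    return(empty_mappings())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop(sprintf("malformed ESP line %d in %s: expected 9 tab-separated fields, got %d",
                 which(nf != 9L)[1], path, nf[nf != 9L][1]))
  }
  mat <- do.call(rbind, fields)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(mat[, col]))
    if (anyNA(v)) {
      stop(sprintf("malformed ESP line %d in %s: non-numeric value '%s'",
                   which(is.na(v))[1], path, mat[which(is.na(v))[1], col]))
    }
    v
  }
  orient <- function(col) {
    v <- mat[, col]
    bad <- !v %in% c("+", "-")
    if (any(bad)) {
      stop(sprintf("malformed ESP line %d in %s: orientation must be '+' or '-'",
                   which(bad)[1], path))
    }
    v
  }
  paired_mappings(
    id = mat[, 1], chrom = mat[, 2],
    left_start = num(3), left_end = num(4), left_orient = orient(5),
    right_start = num(6), right_end = num(7), right_orient = orient(8),
    quality = num(9)
  )
}

.read_sam_bam <- function(path, sam = TRUE) {
  bam <- if (sam) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (!n) {
    warning("no usable records in ", path)
    return(empty_mappings())
  }
  counts <- table(rec$qname)
  paired <- names(counts)[counts == 2L]
  n_unpaired <- sum(counts != 2L)
  if (n_unpaired > 0) {
    warning(sprintf("%d unpaired/multiply-seen read name(s) skipped", n_unpaired))
  }
  keep <- rec$qname %in% paired
  o <- order(rec$qname[keep], rec$pos[keep])
  idx <- which(keep)[o]
  i1 <- idx[seq(1, length(idx), by = 2)]
  i2 <- idx[seq(2, length(idx), by = 2)]
  same_chrom <- as.character(rec$rname[i1]) == as.character(rec$rname[i2])
  if (any(!same_chrom)) {
    message(sprintf("read_mappings: dropped %d inter-chromosomal pair(s)",
                    sum(!same_chrom)))
    i1 <- i1[same_chrom]
    i2 <- i2[same_chrom]
  }
  if (!length(i1)) return(empty_mappings())
  q1 <- rec$mapq[i1]
  q2 <- rec$mapq[i2]
  qual <- pmin(ifelse(is.na(q1), 0, q1), ifelse(is.na(q2), 0, q2))
  paired_mappings(
    id = rec$qname[i1], chrom = as.character(rec$rname[i1]),
    left_start = rec$pos[i1] - 1, left_end = rec$pos[i1] - 1 + rec$qwidth[i1],
    left_orient = ifelse(as.character(rec$strand[i1]) == "-", "-", "+"),
    right_start = rec$pos[i2] - 1, right_end = rec$pos[i2] - 1 + rec$qwidth[i2],
    right_orient = ifelse(as.character(rec$strand[i2]) == "-", "-", "+"),
    quality = qual
  )
}

#' Write mappings in the tab-separated paired-end format
#'
#' @param m Mapping `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(m, path) {
  out <- m[, .esp_cols, drop = FALSE]
  for (col in c("left_start", "left_end", "right_start", "right_end", "quality")) {
    out[[col]] <- format(out[[col]], scientific = FALSE, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write deletion clusters as TSV plus a BED of breakpoint regions
#'
#' @param clusters List of [deletion_cluster] objects.
#' @param path Output TSV path (written with a header).
#' @param bed_path Companion BED (3+1 columns) of breakpoint regions;
#'   defaults to `path` with a `.bed` extension.
#' @param conflicting Character vector of cluster ids involved in at least
#'   one conflict; sets the `conflict_flag` column.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, bed_path = NULL,
                           conflicting = character(0)) {
  df <- clusters_to_df(clusters)
  df$conflict_flag <- df$cluster_id %in% conflicting
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(bed_path)) bed_path <- paste0(sub("\\.tsv$", "", path), ".bed")
  bed <- df[, c("chrom", "br_start", "br_end", "cluster_id")]
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cluster TSV written by [write_clusters()]
#'
#' @param path Cluster TSV path.
#' @return A `data.frame` of cluster fields.
#' @export
read_clusters_df <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(cluster_id = "character", chrom = "character",
                                   source_mix = "character", members = "character"))
}

#' Rebuild cluster objects from a cluster table
#'
#' @param df Data frame as returned by [read_clusters_df()] or
#'   [clusters_to_df()].
#' @return List of [deletion_cluster] objects.
#' @export
clusters_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    br_len <- df$br_end[i] - df$br_start[i]
    structure(list(
      id = df$cluster_id[i],
      members = strsplit(df$members[i], ",", fixed = TRUE)[[1]],
      chrom = df$chrom[i],
      br = c(df$br_start[i], df$br_end[i]),
      del_min = df$del_min[i], del_max = df$del_max[i],
      span_hull = c(df$hull_start[i], df$hull_end[i]),
      support = df$support[i],
      source_mix = list(),
      valid = br_len > 0 && df$del_min[i] <= df$del_max[i] &&
        df$del_min[i] <= br_len
    ), class = "deletion_cluster")
  })
}

#' Write per-mapping assignment labels
#'
#' One row per tumor mapping handled by the component assignments, labelled
#' `refined_normal`, `tumor_specific:<k>`, `concordant_normal`, or
#' `discarded`.
#'
#' @param results List of `assignment_result` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(results, path) {
  rows <- list()
  add <- function(component_id, ids, label) {
    if (length(ids)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        component_id = component_id, mapping_id = ids, label = label,
        stringsAsFactors = FALSE)
    }
  }
  for (res in results) {
    add(res$component_id, res$support_ids, "refined_normal")
    for (k in seq_along(res$tumor_clusters)) {
      cl <- res$tumor_clusters[[k]]
      members <- setdiff(cl$members, res$support_ids)
      add(res$component_id, members, sprintf("tumor_specific:%d", k))
    }
    add(res$component_id, res$normal_concordant_ids, "concordant_normal")
    add(res$component_id, res$discarded_ids, "discarded")
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(component_id = character(0), mapping_id = character(0),
               label = character(0), stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write minimal conflicting sets as TSV
#'
#' @param h A [conflict_hypergraph].
#' @param path Output TSV path.
#' @param triplets Optional list of pairwise-conflicting triples from
#'   [diploid_conflict_triplets()], appended with type
#'   `"diploid_triplet"`.
#' @return `path`, invisibly.
#' @export
write_conflicts <- function(h, path, triplets = list()) {
  df <- data.frame(
    members = c(vapply(h$edges, paste, character(1), collapse = ","),
                vapply(triplets, paste, character(1), collapse = ",")),
    size = c(lengths(h$edges), lengths(triplets)),
    type = c(rep("minimal_conflict", length(h$edges)),
             rep("diploid_triplet", length(triplets))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
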