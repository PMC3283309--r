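# End-to-end pipeline: estimate insert-size cutoffs, cluster the normal
# deletion mappings, check their consistency, build overlapping components
# from the tumor data, and solve the four-copy assignment per component.

#' Run the matched normal/tumor deletion pipeline
#'
#' @param normal,tumor Mapping inputs: file paths (read with `format`) or
#'   mapping `data.frame`s from [paired_mappings()]/[simulate_dataset()].
#' @param format Input format when paths are given (`"esp"`, `"sam"`,
#'   `"bam"`).
#' @param lib_normal,lib_tumor Optional [library_stats]; when `NULL` the
#'   cutoffs are estimated per sample as nearest-rank quantiles
#'   (`q_low`/`q_high`) of the proper-orientation insert lengths.
#' @param min_quality Mapping-quality threshold applied when reading files.
#' @param q_low,q_high Quantile levels for cutoff estimation.
#' @param max_clusters Per-chromosome cap for maximal cluster enumeration.
#' @param time_limit Branch-and-bound budget per component (seconds).
#' @param overlap_on Component seeding overlap test, `"span"` or `"br"`.
#' @param concordant_constrain Treat tumor concordant mappings as blockers
#'   on the tumor copies (stricter; off by default).
#' @param support_threshold Support cutoff used in the summary table.
#' @param out_dir If non-`NULL`, stage outputs (clusters, conflicts,
#'   assignment, summary TSVs and a BED of breakpoint regions) are written
#'   there.
#' @param verbose Print per-stage progress.
#' @return List with the per-stage results: `lib_normal`, `lib_tumor`,
#'   `normal_clusters`, `skipped_chromosomes`, `conflicts` (a
#'   [conflict_hypergraph] over the normal clusters), `diploid_triplets`,
#'   `components`, `dropped_components`, `assignments`, `tumor_clusters`
#'   (all called tumor-specific clusters) and `summary` (a `data.frame`
#'   of cluster/conflict counts per data set).
#' @export
run_pipeline <- function(normal, tumor, format = "esp",
                         lib_normal = NULL, lib_tumor = NULL,
                         min_quality = 20, q_low = 0.001, q_high = 0.999,
                         max_clusters = 1e6, time_limit = 600,
                         overlap_on = "span", concordant_constrain = FALSE,
                         support_threshold = 20,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  load_sample <- function(x, label) {
    m <- if (is.character(x)) {
      read_mappings(x, format = format, min_quality = min_quality,
                    source = label)
    } else {
      x
    }
    m$source <- label
    m
  }
  nm <- load_sample(normal, "normal")
  tm <- load_sample(tumor, "tumor")

  proper_inserts <- function(m) {
    ok <- m$left_orient == "+" & m$right_orient == "-" &
      m$left_start <= m$right_start
    (m$right_end - m$left_start)[ok]
  }
  if (is.null(lib_normal)) {
    lib_normal <- estimate_insert_bounds(proper_inserts(nm), q_low, q_high,
                                         quality_min = min_quality)
  }
  if (is.null(lib_tumor)) {
    lib_tumor <- estimate_insert_bounds(proper_inserts(tm), q_low, q_high,
                                        quality_min = min_quality)
  }
  say("cutoffs: normal [%g, %g], tumor [%g, %g]",
      lib_normal$min_len, lib_normal$max_len,
      lib_tumor$min_len, lib_tumor$max_len)

  nm <- annotate_mappings(nm, lib_normal)
  tm <- annotate_mappings(tm, lib_tumor)

  cl_res <- enumerate_maximal_valid_clusters(nm, max_clusters = max_clusters,
                                             id_prefix = "n")
  normal_clusters <- cl_res$clusters
  say("normal sample: %d deletion mapping(s), %d maximal cluster(s)",
      sum(nm$class == "deletion"), length(normal_clusters))

  nodes <- conflict_nodes(normal_clusters)
  conflicts <- enumerate_minimal_conflicts(nodes)
  triplets <- diploid_conflict_triplets(nodes)

  comp_res <- build_components(normal_clusters, tm, overlap_on = overlap_on)
  say("%d overlapping component(s), %d dropped",
      length(comp_res$components), nrow(comp_res$dropped))

  cluster_by_id <- stats::setNames(normal_clusters,
                                   vapply(normal_clusters, function(cl) cl$id,
                                          character(1)))
  assignments <- lapply(comp_res$components, function(comp) {
    assign_component(comp, cluster_by_id[[comp$normal_cluster_id]], tm,
                     time_limit = time_limit,
                     concordant_constrain = concordant_constrain)
  })
  tumor_clusters <- unlist(lapply(assignments, function(r) r$tumor_clusters),
                           recursive = FALSE)
  if (is.null(tumor_clusters)) tumor_clusters <- list()
  say("%d tumor-specific cluster(s), %d discarded mapping(s)",
      length(tumor_clusters),
      sum(vapply(assignments, function(r) r$n_discarded, numeric(1))))

  conflicting_ids <- unique(unlist(c(conflicts$edges, triplets)))
  t_nodes <- conflict_nodes(tumor_clusters)
  t_conflicts <- enumerate_minimal_conflicts(t_nodes)
  t_triplets <- diploid_conflict_triplets(t_nodes)
  t_conflicting <- unique(unlist(c(t_conflicts$edges, t_triplets)))

  summarize <- function(dataset, clusters, confl_ids) {
    supp <- vapply(clusters, function(cl) cl$support, numeric(1))
    ids <- vapply(clusters, function(cl) cl$id, character(1))
    if (!length(clusters)) supp <- numeric(0)
    big <- supp >= support_threshold
    data.frame(
      dataset = dataset,
      deletions = length(clusters),
      conflicting = sum(ids %in% confl_ids),
      conflicting_pct = if (length(clusters)) {
        round(100 * sum(ids %in% confl_ids) / length(clusters), 1)
      } else {
        NA_real_
      },
      deletions_ge_threshold = sum(big),
      conflicting_ge_threshold = sum(big & ids %in% confl_ids),
      stringsAsFactors = FALSE
    )
  }
  summary <- rbind(
    summarize("normal", normal_clusters, conflicting_ids),
    summarize("tumor_specific", tumor_clusters, t_conflicting)
  )

  res <- list(
    lib_normal = lib_normal, lib_tumor = lib_tumor,
    normal_mappings = nm, tumor_mappings = tm,
    normal_clusters = normal_clusters,
    skipped_chromosomes = cl_res$skipped,
    conflicts = conflicts, diploid_triplets = triplets,
    components = comp_res$components,
    dropped_components = comp_res$dropped,
    assignments = assignments,
    tumor_clusters = tumor_clusters,
    summary = summary
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_clusters(normal_clusters, file.path(out_dir, "normal_clusters.tsv"),
                   conflicting = conflicting_ids)
    write_clusters(tumor_clusters, file.path(out_dir, "tumor_clusters.tsv"),
                   conflicting = t_conflicting)
    write_conflicts(conflicts, file.path(out_dir, "conflicts.tsv"),
                    triplets = triplets)
    write_assignment(assignments, file.path(out_dir, "assignment.tsv"))
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
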