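# Pipeline orchestration: configuration handling, the end-to-end run
# producing the full report bundle, and the identity-table report.

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext)
}

default_pipeline_params <- function() {
  list(
    ksa = list(k_min = 10, k_max = 16, min_score = 0.8),
    align = list(match = 2, mismatch = -1, gap_open = -10, gap_extend = -4),
    assign = list(min_identity = 70),
    profiles = list(w = 15, s = 2, k = 2, min_run = 2),
    motifs = list(L_min = 15, L_max = 25, min_cross_identity = 85,
                  min_breadth = 3),
    cenpb = list(consensus = "CTTCGTTGGAAACGGGA",
                 essential_positions = c(2, 3, 4, 5, 10, 13, 14, 15, 16)),
    hor = list(band = 15, min_fragment = 25, reanalyze_below = 90, tol = 3,
               n_perm = 10000, overlap_min_len = 30, overlap_min_identity = 85),
    tree = list(bootstrap = 100))
}

#' Lay out a Table-1-style group identity report
#'
#' Lower-triangular layout with `mean (sd)` cells and a per-group `n` column.
#'
#' @param im An `identity_matrix` from [group_identity_matrix()], or a named
#'   list of groups (then the matrix is computed first).
#' @param path Optional output TSV path.
#' @param params [align_params()] (used only when groups are given).
#' @return A data.frame (invisibly when written to `path`).
#' @export
make_identity_table <- function(im, path = NULL, params = align_params()) {
  if (!inherits(im, "identity_matrix")) im <- group_identity_matrix(im, params)
  k <- length(im$labels)
  cells <- matrix("", k, k, dimnames = list(im$labels, im$labels))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    cells[i, j] <- if (is.na(im$mean[i, j])) "NA" else
      sprintf("%.1f (%.1f)", im$mean[i, j], im$sd[i, j])
  }
  df <- data.frame(group = im$labels, n = unname(im$n),
                   as.data.frame(cells), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(c("# group identity matrix: mean percent identity (population SD)",
                 "# lower triangle; diagonal = within-group"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(invisible(df))
  }
  df
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration over a set of array sequences and a family
#' library: Key-String segmentation report, monomer tiling and GFF3
#' annotations, group identity matrix TSV, neighbor-joining tree with
#' bootstrap supports (Newick), per-site variability profile with windows
#' (TSV) and conserved domains (BED), shared boxes with CENP-B scores
#' (JSON), and HOR/junction report (TSV). All stage parameters and the seed
#' are resolved into the output bundle.
#'
#' @param arrays Named character vector / `DNAStringSet` of array sequences,
#'   or a path to a FASTA file.
#' @param families Named character vector / `DNAStringSet` of family
#'   consensuses (a spacer consensus may be included), or a FASTA path.
#' @param out_dir Output directory for the report bundle (`NULL` for none).
#' @param params Nested parameter list; defaults from
#'   `default_pipeline_params()` are used for anything missing.
#' @param seed Master seed for the seeded stages (bootstrap, permutation
#'   test).
#' @return List with the in-memory results of every stage (and `paths` when
#'   written).
#' @export
run_full <- function(arrays, families, out_dir = NULL, params = list(),
                     seed = 1) {
  if (is.character(arrays) && length(arrays) == 1L && file.exists(arrays))
    arrays <- read_fasta(arrays)
  if (is.character(families) && length(families) == 1L && file.exists(families))
    families <- read_fasta(families)
  arrays <- as_named_chr(arrays)
  families <- as_named_chr(families)
  p <- utils::modifyList(default_pipeline_params(), params)
  ap <- do.call(align_params, p$align)
  log_lines <- c(sprintf("satarray run: %d array(s), %d family consensus(es), seed %d",
                         length(arrays), length(families), seed))

  # --- KSA segmentation report -------------------------------------------
  key <- select_key(arrays, k_min = p$ksa$k_min, k_max = p$ksa$k_max,
                    min_score = p$ksa$min_score)
  ksa_report <- if (is.null(key)) {
    log_lines <- c(log_lines, "ksa: no periodic key found")
    data.frame(seq_id = character(), key = character(), score = numeric(),
               n_complete = integer(), modal_length = integer())
  } else {
    log_lines <- c(log_lines, sprintf(
      "ksa: key %s (score %.3f, modal length %d)", key$key, key$score,
      key$modal_length))
    do.call(rbind, lapply(names(arrays), function(nm) {
      sg <- segment_by_key(arrays[[nm]], key$key)
      lens <- with(sg$segments, end[flag == "complete"] - start[flag == "complete"])
      data.frame(seq_id = nm, key = key$key,
                 score = key_periodicity_score(sg),
                 n_complete = length(lens),
                 modal_length = if (length(lens)) as.integer(names(which.max(table(lens)))) else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }

  # --- shared boxes on the family consensuses ----------------------------
  fam_only <- families  # spacers participate; they simply never carry boxes
  boxes <- find_shared_boxes(fam_only, L_min = p$motifs$L_min,
                             L_max = p$motifs$L_max,
                             min_cross_identity = p$motifs$min_cross_identity,
                             min_breadth = p$motifs$min_breadth)
  cenpb <- do.call(cenpb_reference, p$cenpb)
  box_table <- list()
  for (b in boxes) for (i in seq_len(nrow(b$instances))) {
    f <- b$instances$family[i]
    box_table[[f]] <- c(box_table[[f]] %||% list(),
                        setNames(list(c(b$instances$start[i], b$instances$end[i])),
                                 b$name))
  }
  models <- family_model_set(families, box_table)

  # --- tiling annotation --------------------------------------------------
  annotations <- do.call(rbind, lapply(names(arrays), function(nm)
    as.data.frame(tile_annotate(arrays[[nm]], models,
                                min_identity = p$assign$min_identity,
                                params = ap, band = p$hor$band,
                                min_fragment = p$hor$min_fragment,
                                reanalyze_below = p$hor$reanalyze_below,
                                seq_id = nm))))
  class(annotations) <- c("monomer_annotations", "data.frame")
  log_lines <- c(log_lines, sprintf(
    "tiling: %d monomer(s), %d unassigned segment(s)",
    sum(!is.na(annotations$family)), sum(is.na(annotations$family))))

  # --- monomer extraction, identity matrix, tree, profile ----------------
  ann_ok <- annotations[!is.na(annotations$family) &
                          annotations$partial == "none", , drop = FALSE]
  monomers <- character(0); mon_groups <- character(0)
  for (i in seq_len(nrow(ann_ok))) {
    s <- substr(arrays[[ann_ok$seq_id[i]]], ann_ok$start[i] + 1L, ann_ok$end[i])
    s <- rotate_seq(s, -ann_ok$register_offset[i])  # back to standard register
    monomers <- c(monomers, s)
    mon_groups <- c(mon_groups, ann_ok$family[i])
  }
  names(monomers) <- sprintf("%s_%03d", mon_groups, seq_along(monomers))
  groups <- split(monomers, mon_groups)
  groups <- groups[lengths(groups) >= 2L]
  identity <- if (length(groups) >= 2L) group_identity_matrix(groups, ap) else NULL
  tree <- NULL
  if (length(monomers) >= 4L) {
    msa <- center_star_msa(monomers, ap)
    tree <- bootstrap_support(msa, B = p$tree$bootstrap,
                              seed = derive_seed(seed, "bootstrap"))
    profile <- sliding_window(site_majority_profile(msa),
                              w = p$profiles$w, s = p$profiles$s)
    domains <- call_conserved_domains(profile, k = p$profiles$k,
                                      min_run = p$profiles$min_run)
  } else { msa <- NULL; profile <- NULL; domains <- NULL }

  # --- junctions, HOR units, events --------------------------------------
  junctions <- extract_junctions(annotations)
  coloc <- if (nrow(junctions) > 0L && length(boxes) > 0L)
    box_colocation_test(junctions, models, tol = p$hor$tol,
                        n_perm = p$hor$n_perm,
                        seed = derive_seed(seed, "coloc")) else NULL
  replacements <- detect_box1_replacement(annotations, models, tol = p$hor$tol)
  overlaps <- detect_overlap_junction(annotations, models, arrays,
                                      min_len = p$hor$overlap_min_len,
                                      min_identity = p$hor$overlap_min_identity,
                                      params = ap)
  hor_units <- lapply(names(arrays), function(nm) {
    labels <- annotation_labels(annotations[annotations$seq_id == nm, ])
    if (length(labels) < 2L) return(NULL)
    u <- infer_hor_unit(labels, lengths = nchar(families))
    list(seq_id = nm, classification = classify_array(labels), unit = u)
  })
  hor_units <- Filter(Negate(is.null), hor_units)

  out <- list(ksa = ksa_report, boxes = boxes, models = models,
              annotations = annotations, identity = identity, tree = tree,
              profile = profile, domains = domains,
              junctions = if (is.null(coloc)) junctions else coloc$junctions,
              colocation = coloc, replacements = replacements,
              overlaps = overlaps, hor_units = hor_units,
              params = p, seed = seed, log = log_lines)

  if (!is.null(out_dir)) out$paths <- write_bundle(out, arrays, out_dir)
  out
}

write_bundle <- function(res, arrays, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  w <- function(name) file.path(out_dir, name)

  paths$ksa <- w("ksa_report.tsv")
  utils::write.table(res$ksa, paths$ksa, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(res$identity)) {
    paths$identity <- w("identity_matrix.tsv")
    make_identity_table(res$identity, paths$identity)
  }
  if (!is.null(res$tree)) {
    paths$tree <- w("tree.nwk")
    tr <- res$tree
    # Newick reserves quotes and punctuation; keep tip labels plain
    tr$tip.label <- gsub("[^A-Za-z0-9_.-]", "_", tr$tip.label)
    ape::write.tree(tr, paths$tree)
  }
  if (!is.null(res$profile)) {
    paths$profile_sites <- w("variability_sites.tsv")
    utils::write.table(
      data.frame(site = res$profile$site_index,
                 P = res$profile$site_values),
      paths$profile_sites, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$profile_windows <- w("variability_windows.tsv")
    utils::write.table(
      data.frame(window_start = res$profile$window_starts,
                 mean_P = res$profile$window_values),
      paths$profile_windows, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$domains <- w("conserved_domains.bed")
    bed <- if (is.null(res$domains) || nrow(res$domains) == 0L)
      data.frame(chrom = character(), start = integer(), end = integer())
    else data.frame(chrom = "consensus", start = res$domains$start,
                    end = res$domains$end)
    utils::write.table(bed, paths$domains, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  paths$boxes <- w("boxes.json")
  write_boxes_json(res$boxes, paths$boxes,
                   cenpb = do.call(cenpb_reference, res$params$cenpb))
  paths$gff3 <- w("monomers.gff3")
  write_annotations_gff3(res$annotations, paths$gff3,
                         seqlens = setNames(nchar(arrays), names(arrays)))
  paths$junctions <- w("junctions.tsv")
  utils::write.table(res$junctions, paths$junctions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$hor <- w("hor_units.tsv")
  hor_df <- do.call(rbind, lapply(res$hor_units, function(h)
    data.frame(seq_id = h$seq_id, classification = h$classification,
               unit = paste(h$unit$labels, collapse = "-"),
               period = h$unit$period, variant = h$unit$variant,
               stringsAsFactors = FALSE)))
  utils::write.table(hor_df %||% data.frame(), paths$hor, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$config <- w("config_resolved.yaml")
  yaml::write_yaml(c(res$params, list(seed = res$seed)), paths$config)
  paths$log <- w("log.txt")
  writeLines(res$log, paths$log)
  paths
}
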