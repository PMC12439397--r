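#' Write a cell dataset as a 10x-style directory
#'
#' Writes `matrix.mtx` (Matrix Market coordinate format, 1-based indices),
#' `features.tsv` (gene id, symbol, mito flag), `barcodes.tsv`, `cells.tsv`
#' (barcode, patient, group, cell_type), and, when ground truth is present,
#' `truth.tsv`.  Gene and cell order is preserved, so a read/write
#' round-trip is lossless.
#'
#' @param dataset A `cell_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(dataset$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(dataset$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(dataset$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth) && nrow(dataset$truth$effects)) {
    utils::write.table(dataset$truth$effects, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a 10x-style directory into a cell dataset
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `cells.tsv` as
#' written by [write_cell_matrix()]; dimensions, barcode sets and gene ids
#' are validated with descriptive errors.
#'
#' @param dir Directory containing the files.
#' @return A `cell_dataset` (without simulation truth unless `truth.tsv`
#'   exists).
#' @export
read_cell_matrix <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files)) {
    stop("missing file(s) in ", dir, ": ",
         paste(missing_files, collapse = ", "))
  }
  counts <- tryCatch(
    methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix"),
    error = function(e) stop("malformed matrix.mtx: ", conditionMessage(e)))
  features <- utils::read.delim(file.path(dir, "features.tsv"),
                                stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cells <- tibble::as_tibble(utils::read.delim(file.path(dir, "cells.tsv"),
                                               stringsAsFactors = FALSE))
  if (nrow(features) != nrow(counts)) {
    stop("matrix.mtx declares ", nrow(counts), " genes but features.tsv lists ",
         nrow(features))
  }
  if (length(barcodes) != ncol(counts)) {
    stop("matrix.mtx declares ", ncol(counts), " cells but barcodes.tsv lists ",
         length(barcodes))
  }
  if (anyDuplicated(features$gene_id)) {
    stop("duplicate gene ids in features.tsv: ",
         paste(utils::head(features$gene_id[duplicated(features$gene_id)], 3),
               collapse = ", "))
  }
  unknown <- setdiff(cells$barcode, barcodes)
  if (length(unknown)) {
    stop("cells.tsv contains barcode(s) absent from barcodes.tsv: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  dimnames(counts) <- list(features$gene_id, barcodes)
  cells <- cells[match(barcodes, cells$barcode), , drop = FALSE]
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv"))) {
    eff <- tibble::as_tibble(utils::read.delim(file.path(dir, "truth.tsv"),
                                               stringsAsFactors = FALSE))
    truth <- list(effects = eff,
                  null_cell_types = setdiff(unique(cells$cell_type),
                                            unique(eff$cell_type)),
                  homogeneity = NULL)
  }
  structure(list(counts = counts,
                 features = tibble::as_tibble(features),
                 cells = cells, truth = truth),
            class = "cell_dataset")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Duplicate members within a set are deduplicated; lines with fewer than
#' three fields raise an error naming the line.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Run configuration holding every pipeline threshold
#'
#' Bundles the stage parameters of the whole pipeline: QC bounds, the
#' minimum supporting-cell rule, per-group patient minimum, FDR cutoffs,
#' signature size, number of sampled cell pairs, variable-gene count, the
#' integration toggle and the seed.  Round-trips losslessly through YAML
#' via [write_run_config()] / [read_run_config()].
#'
#' @param qc A [qc_params()] object.
#' @param min_cells Minimum supporting cells per pseudobulk entry.
#' @param min_patients_per_group Per-group patient minimum for testing a
#'   gene (4, or 3 for reduced cohorts).
#' @param fdr_cutoffs FDR cutoffs for reporting.
#' @param n_top_signature Signature size per cell type.
#' @param n_cell_pairs Sampled cell pairs per sample pair.
#' @param n_hvg Number of variable genes to keep (`NULL` = all).
#' @param center_batches Apply the per-patient centering stand-in before
#'   masking (`FALSE` reruns the pipeline on non-integrated data).
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(qc = qc_params(),
                       min_cells = 10,
                       min_patients_per_group = 4,
                       fdr_cutoffs = c(0.05, 0.1, 0.2),
                       n_top_signature = 50,
                       n_cell_pairs = 100,
                       n_hvg = NULL,
                       center_batches = TRUE,
                       seed = 1L) {
  stopifnot(min_cells >= 0, min_patients_per_group >= 1,
            all(fdr_cutoffs > 0 & fdr_cutoffs < 1),
            n_top_signature >= 1, n_cell_pairs >= 1)
  structure(list(qc = qc, min_cells = min_cells,
                 min_patients_per_group = as.integer(min_patients_per_group),
                 fdr_cutoffs = fdr_cutoffs,
                 n_top_signature = as.integer(n_top_signature),
                 n_cell_pairs = as.integer(n_cell_pairs),
                 n_hvg = if (is.null(n_hvg)) NULL else as.integer(n_hvg),
                 center_batches = isTRUE(center_batches),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$qc <- unclass(lst$qc)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  qc <- do.call(qc_params, lst$qc)
  do.call(run_config, c(list(qc = qc), lst[setdiff(names(lst), "qc")]))
}

#' Write a pseudobulk tensor as TSV files
#'
#' One `<cell type>.values.tsv` (genes x patients, literal `NA` for missing
#' entries, 6 significant digits) and one `<cell type>.ncells.tsv` per cell
#' type, plus `groups.tsv`.
#'
#' @param pb A [pseudobulk()] object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pseudobulk <- function(pb, dir) {
  stopifnot(inherits(pb, "pseudobulk"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(pb$values)) {
    v <- format(signif(pb$values[[ct]], 6), trim = TRUE)
    v[is.na(pb$values[[ct]])] <- "NA"
    utils::write.table(cbind(gene = rownames(pb$values[[ct]]), v),
                       file.path(dir, paste0(ct, ".values.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(gene = rownames(pb$n_cells[[ct]]),
                             pb$n_cells[[ct]]),
                       file.path(dir, paste0(ct, ".ncells.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(tibble::tibble(patient = names(pb$groups),
                                    group = unname(pb$groups)),
                     file.path(dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Export a dendrogram with stability annotations
#'
#' Writes a Newick file (node comments carry BP/AU when a
#' [bootstrap_stability()] table is given) and a TSV of per-node leaf
#' memberships.
#'
#' @param dend An `hclust` object from [hcluster()].
#' @param path Output path for the Newick file; the membership table goes
#'   to `<path>.nodes.tsv`.
#' @param stability Optional [bootstrap_stability()] result.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dend, path, stability = NULL) {
  phy <- ape::as.phylo(dend)
  if (!is.null(stability)) {
    # ape internal node order: match by membership sets
    memb <- node_members(dend$merge)
    keys <- vapply(memb, function(m) paste(sort(dend$labels[m]), collapse = ","),
                   character(1))
    stab_keys <- vapply(strsplit(stability$members, ","),
                        function(m) paste(sort(m), collapse = ","), character(1))
    node_lab <- character(phy$Nnode)
    for (k in seq_len(phy$Nnode)) {
      tips <- ape::extract.clade(phy, k + ape::Ntip(phy))$tip.label
      key <- paste(sort(tips), collapse = ",")
      hit <- match(key, stab_keys)
      if (!is.na(hit)) {
        node_lab[k] <- sprintf("bp%.0f_au%.0f",
                               stability$bp[hit], stability$au[hit])
      }
    }
    phy$node.label <- node_lab
  }
  ape::write.tree(phy, file = path)
  memb_tab <- tibble::tibble(
    node = seq_len(nrow(dend$merge)),
    height = signif(dend$height, 6),
    members = vapply(node_members(dend$merge),
                     function(m) paste(dend$labels[m], collapse = ","),
                     character(1)))
  utils::write.table(memb_tab, paste0(path, ".nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
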