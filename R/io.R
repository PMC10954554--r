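## Delimited-text readers/writers for the analysis tables and Newick trees.
## All tables are UTF-8, tab-separated, with a header row.

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  x
}

default_meta_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", ".meta\\1", path)
}

#' Read age-at-death datasets from a delimited table
#'
#' The main table has columns `dataset_id, species, sex, population_id, age,
#' count`; a metadata sidecar table (default: the main path with `.meta`
#' inserted before the extension) has one row per `dataset_id` with columns
#' `growth_prior_mean, growth_prior_sd, bias_window_lo, bias_window_hi,
#' age_bias_offset, source_type`. Datasets absent from the sidecar get the
#' defaults: growth prior (0, 0.05), no bias window, `B = 0`.
#'
#' @param path path to the main table.
#' @param meta_path path to the metadata sidecar, or `NULL` for the default.
#' @return A list of [age_dataset] objects, one per `dataset_id`.
#' @seealso [write_age_datasets()]
#' @export
read_age_datasets <- function(path, meta_path = NULL) {
  x <- read_table_checked(path, c("dataset_id", "species", "sex",
                                  "population_id", "age", "count"))
  if (any(x$age < 0)) {
    stop("negative age at row ", which(x$age < 0)[1], call. = FALSE)
  }
  if (any(x$count < 0)) {
    stop("negative count at row ", which(x$count < 0)[1], call. = FALSE)
  }
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(dataset_id = character())
  }
  lapply(split(x, x$dataset_id), function(d) {
    m <- meta[match(d$dataset_id[1], meta$dataset_id), , drop = FALSE]
    has <- function(col) nrow(m) == 1 && col %in% names(m) && !is.na(m[[col]])
    bw <- if (has("bias_window_lo") && has("bias_window_hi")) {
      c(m$bias_window_lo, m$bias_window_hi)
    } else NULL
    age_dataset(
      dataset_id = d$dataset_id[1], species = d$species[1], sex = d$sex[1],
      population_id = d$population_id[1],
      ages = d$age, counts = d$count,
      growth_prior = c(if (has("growth_prior_mean")) m$growth_prior_mean else 0,
                       if (has("growth_prior_sd")) m$growth_prior_sd else 0.05),
      bias_window = bw,
      age_bias_offset = if (has("age_bias_offset")) m$age_bias_offset else 0,
      source_type = if (has("source_type")) m$source_type else "unknown")
  })
}

#' Write age-at-death datasets and their metadata sidecar
#'
#' @param datasets list of [age_dataset] objects.
#' @param path main table path; the sidecar goes to `meta_path`.
#' @param meta_path sidecar path, or `NULL` for the default.
#' @return Invisibly, `path`.
#' @export
write_age_datasets <- function(datasets, path, meta_path = NULL) {
  if (inherits(datasets, "age_dataset")) datasets <- list(datasets)
  main <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(dataset_id = d$dataset_id, species = d$species, sex = d$sex,
               population_id = d$population_id,
               age = d$records$observed_age, count = d$records$count)
  }))
  meta <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(dataset_id = d$dataset_id,
               growth_prior_mean = d$growth_prior[1],
               growth_prior_sd = d$growth_prior[2],
               bias_window_lo = if (is.null(d$bias_window)) NA else d$bias_window[1],
               bias_window_hi = if (is.null(d$bias_window)) NA else d$bias_window[2],
               age_bias_offset = d$age_bias_offset,
               source_type = d$source_type)
  }))
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  utils::write.table(main, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ovarian corpora datasets
#'
#' Expects columns `dataset_id, species, age, corpora_count, age_at_maturity`
#' and optionally `max_lifespan_age` (maximum observed age from the lifespan
#' database, used for the sampling-rate filter; defaults to the within-dataset
#' maximum age).
#'
#' @param path path to the table.
#' @return A list of [corpora_dataset] objects.
#' @export
read_corpora_datasets <- function(path) {
  x <- read_table_checked(path, c("dataset_id", "species", "age",
                                  "corpora_count", "age_at_maturity"))
  lapply(split(x, x$dataset_id), function(d) {
    mla <- if ("max_lifespan_age" %in% names(d) && !is.na(d$max_lifespan_age[1])) {
      d$max_lifespan_age[1]
    } else max(d$age)
    corpora_dataset(d$dataset_id[1], d$species[1], d$age, d$corpora_count,
                    age_at_maturity = d$age_at_maturity[1],
                    max_lifespan_age = mla)
  })
}

#' @rdname read_corpora_datasets
#' @param datasets list of [corpora_dataset] objects to write.
#' @export
write_corpora_datasets <- function(datasets, path) {
  if (inherits(datasets, "corpora_dataset")) datasets <- list(datasets)
  x <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(dataset_id = d$dataset_id, species = d$species,
               age = d$records$age, corpora_count = d$records$corpora_count,
               age_at_maturity = d$age_at_maturity,
               max_lifespan_age = d$n / d$sampling_rate)
  }))
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species trait tables
#'
#' Expects columns `species, sex, length_mean, maturity_mean, menopause` and
#' optionally `length_sd, maturity_sd, juvenile_sample_size`. Missing
#' standard deviations default to 0 with a warning (the trait is then treated
#' as measured without error).
#'
#' @param path path to the table.
#' @return A list of [species_traits] objects.
#' @export
read_traits <- function(path) {
  x <- read_table_checked(path, c("species", "sex", "length_mean",
                                  "maturity_mean", "menopause"))
  for (col in c("length_sd", "maturity_sd")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
    if (anyNA(x[[col]])) {
      warning("missing ", col, " set to 0 for ",
              sum(is.na(x[[col]])), " species", call. = FALSE)
      x[[col]][is.na(x[[col]])] <- 0
    }
  }
  if (!"juvenile_sample_size" %in% names(x)) x$juvenile_sample_size <- 0L
  lapply(seq_len(nrow(x)), function(i) {
    species_traits(x$species[i], x$sex[i], x$length_mean[i], x$length_sd[i],
                   x$maturity_mean[i], x$maturity_sd[i], x$menopause[i],
                   x$juvenile_sample_size[i])
  })
}

#' @rdname read_traits
#' @param traits list of [species_traits] to write.
#' @export
write_traits <- function(traits, path) {
  x <- do.call(rbind, lapply(traits, function(t) {
    data.frame(species = t$species, sex = t$sex,
               length_mean = t$length_mean, length_sd = t$length_sd,
               maturity_mean = t$maturity_mean, maturity_sd = t$maturity_sd,
               menopause = t$menopause,
               juvenile_sample_size = t$juvenile_sample_size)
  }))
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time-calibrated chronograms from a multi-tree Newick file
#'
#' @param path Newick file with one or more trees.
#' @param required_taxa optional character vector; an error lists any taxa
#'   absent from any tree.
#' @param tol relative ultrametricity tolerance passed to [chronogram()].
#' @return A list of [chronogram] objects.
#' @export
read_trees <- function(path, required_taxa = NULL, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees in ", path, call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- lapply(seq_along(trees), function(i) chronogram(trees[[i]], i, tol = tol))
  if (!is.null(required_taxa)) {
    for (ch in out) {
      absent <- setdiff(required_taxa, ch$taxa)
      if (length(absent)) {
        stop("tree ", ch$tree_index, " is missing taxa: ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
    }
  }
  out
}
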