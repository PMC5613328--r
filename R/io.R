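# Plain-text serialization: phenome/effect tables and population snapshots
# as TSV, configs as YAML, run summaries as TSV with a metadata header.

#' Write phenomes and effect scores to a TSV audit table
#'
#' One row per OTU: `otu_id`, the phenome's trait indices comma-joined, and
#' the host- and microbe-effect scores of those traits, comma-joined in the
#' same order.
#'
#' @param phenomes integer phenome matrix.
#' @param effects effect table from [effect_table()].
#' @param path output file.
#' @export
write_phenome_table <- function(phenomes, effects, path) {
  df <- data.frame(
    otu_id = seq_len(nrow(phenomes)),
    trait_ids = apply(phenomes, 1, paste, collapse = ","),
    host_effects = apply(phenomes, 1,
                         function(tr) paste(effects$host[tr], collapse = ",")),
    microbe_effects = apply(phenomes, 1,
                            function(tr) paste(effects$microbe[tr], collapse = ",")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenome audit table back
#'
#' Reconstructs the phenome matrix and the universal effect vectors from a
#' [write_phenome_table()] file. Trait indices never covered by any phenome
#' come back as `NA` in the effect vectors; inconsistent scores for the same
#' trait are an error.
#'
#' @param path file written by [write_phenome_table()].
#' @param n_traits trait-pool size; `NULL` infers the maximum index seen.
#' @return list with `phenomes`, and effect vectors `host` and `microbe`.
#' @export
read_phenome_table <- function(path, n_traits = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  split_int <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  phen_list <- lapply(df$trait_ids, split_int)
  m <- unique(lengths(phen_list))
  if (length(m) != 1) stop("phenomes of unequal size in ", path)
  phenomes <- do.call(rbind, phen_list)
  if (is.null(n_traits)) n_traits <- max(phenomes)
  rebuild <- function(col) {
    v <- rep(NA_integer_, n_traits)
    for (i in seq_len(nrow(phenomes))) {
      sc <- split_int(col[i])
      tr <- phenomes[i, ]
      clash <- !is.na(v[tr]) & v[tr] != sc
      if (any(clash))
        stop("inconsistent effect scores for trait(s) ",
             paste(tr[clash], collapse = ", "))
      v[tr] <- sc
    }
    v
  }
  list(phenomes = phenomes,
       host = rebuild(df$host_effects),
       microbe = rebuild(df$microbe_effects))
}

#' Write a population snapshot as a host x OTU TSV matrix
#'
#' Columns `host_id`, `lineage`, then one count column per OTU.
#'
#' @param pop a `holosim_population`.
#' @param path output file.
#' @export
write_population_tsv <- function(pop, path) {
  df <- data.frame(host_id = seq_len(nrow(pop$counts)),
                   lineage = pop$lineage, pop$counts)
  names(df)[-(1:2)] <- paste0("otu_", seq_len(ncol(pop$counts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population snapshot count matrix
#'
#' @param path file written by [write_population_tsv()].
#' @return list with `counts` (host x OTU matrix) and `lineage`.
#' @export
read_population_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  counts <- as.matrix(df[, grep("^otu_", names(df)), drop = FALSE])
  dimnames(counts) <- NULL
  list(counts = counts, lineage = df$lineage)
}

#' Write a population snapshot in sparse triplet form
#'
#' One row per nonzero cell: `host_id`, `otu_id`, `count`.
#'
#' @inheritParams write_population_tsv
#' @export
write_population_triplets <- function(pop, path) {
  nz <- which(pop$counts > 0, arr.ind = TRUE)
  df <- data.frame(host_id = nz[, 1], otu_id = nz[, 2],
                   count = pop$counts[nz])
  df <- df[order(df$host_id, df$otu_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse triplet snapshot back into a count matrix
#'
#' @param path file written by [write_population_triplets()].
#' @param n_hosts,n_otu matrix dimensions; `NULL` infers the maxima seen.
#' @return host x OTU count matrix.
#' @export
read_population_triplets <- function(path, n_hosts = NULL, n_otu = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (is.null(n_hosts)) n_hosts <- max(df$host_id)
  if (is.null(n_otu)) n_otu <- max(df$otu_id)
  counts <- matrix(0, n_hosts, n_otu)
  counts[cbind(df$host_id, df$otu_id)] <- df$count
  counts
}

#' Load a simulation configuration from YAML
#'
#' Fields in the file override the [sim_config()] defaults; unknown fields
#' are an error. Because bare `N` is a YAML 1.1 boolean, the file uses the
#' long names `n_hosts`, `capacity` and `n_otus` for `N`, `C` and `M`.
#'
#' @param path YAML file of `sim_config` fields.
#' @return a [sim_config()].
#' @export
read_config_yaml <- function(path) {
  fields <- normalize_config_names(yaml::read_yaml(path))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, fields)
}

# YAML files spell N, C, M as n_hosts, capacity, n_otus
normalize_config_names <- function(fields) {
  long_names <- c(n_hosts = "N", capacity = "C", n_otus = "M")
  hit <- names(fields) %in% names(long_names)
  names(fields)[hit] <- long_names[names(fields)[hit]]
  fields
}

config_metadata <- function(cfg) {
  keys <- c("N", "C", "M", "n_traits", "m", "ma_percent", "me_percent",
            "s_h", "s_m", "microbial_mode", "generations", "acquisition")
  paste(vapply(keys, function(k) paste0(k, "=", format(cfg[[k]])), ""),
        collapse = ";")
}

#' Write a run's summary time series to TSV
#'
#' Machine-readable `#`-prefixed metadata header (package version, seed,
#' flattened configuration) followed by one row per recorded generation.
#'
#' @param run a `holosim_run`.
#' @param path output file.
#' @export
write_run_tsv <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# holosim ", as.character(utils::packageVersion("holosim"))),
    paste0("# seed: ", if (is.null(run$seed)) "NA" else run$seed),
    paste0("# config: ", config_metadata(run$config))), con)
  utils::write.table(run$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a run summary TSV back
#'
#' @param path file written by [write_run_tsv()].
#' @return data frame of the summary rows; metadata lines are attached as
#'   attribute `"metadata"`.
#' @export
read_run_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE)
  attr(df, "metadata") <- meta
  df
}
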