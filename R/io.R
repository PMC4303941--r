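#' Study design for a salt-restriction isolation time course
#'
#' Builds the per-week design table of the cohort: the daily NaCl dose, an
#' isolation flag and the reference phase label. Weeks are integers with
#' week 1 = first isolation week; pre-isolation samples carry indices <= 0
#' and post-isolation samples indices > 15. The default schedule follows the
#' 105-day protocol: 12 g/day in weeks 1-5, 9 g/day in weeks 6-9, 12 g/day in
#' week 10 and 6 g/day in weeks 11-15. Reference phases are early (week <= 6,
#' including pre-isolation), intermediate (weeks 7-11) and late (week >= 12,
#' including post-isolation).
#'
#' @param weeks Integer vector of week indices (default -4..18: five
#'   pre-isolation, fifteen isolation and three post-isolation weeks).
#' @return A tibble with columns `week`, `salt_g_day`, `isolation`, `phase`.
#' @export
#' @examples
#' design <- study_design()
#' table(design$phase)
study_design <- function(weeks = -4:18) {
  weeks <- as.integer(weeks)
  if (anyDuplicated(weeks)) abort("`weeks` must be unique")
  weeks <- sort(weeks)
  salt <- rep(NA_real_, length(weeks))
  salt[weeks >= 1 & weeks <= 5] <- 12
  salt[weeks >= 6 & weeks <= 9] <- 9
  salt[weeks == 10] <- 12
  salt[weeks >= 11 & weeks <= 15] <- 6
  tibble(
    week = weeks,
    salt_g_day = salt,
    isolation = weeks >= 1 & weeks <= 15,
    phase = phase_of_week(weeks)
  )
}

#' Reference phase of a week index
#'
#' @param week Integer week vector (week 1 = first isolation week).
#' @return Character vector in `early`, `intermediate`, `late`.
#' @export
phase_of_week <- function(week) {
  dplyr::case_when(
    week <= 6 ~ "early",
    week <= 11 ~ "intermediate",
    TRUE ~ "late"
  )
}

new_volunteer_matrix <- function(volunteer_id, values, weeks) {
  storage.mode(values) <- "integer"
  structure(
    list(volunteer_id = volunteer_id, values = values, weeks = as.integer(weeks)),
    class = "volunteer_matrix"
  )
}

#' Construct a per-volunteer binary presence matrix
#'
#' @param volunteer_id Label of the volunteer.
#' @param values Numeric/integer matrix of 0/1 detections, proteins in rows
#'   (rownames = accessions), weeks in columns.
#' @param weeks Integer week indices, one per column, strictly increasing.
#' @return A `volunteer_matrix` object.
#' @export
volunteer_matrix <- function(volunteer_id, values, weeks) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) abort("`values` must have protein accessions as rownames")
  if (anyDuplicated(rownames(values))) abort("duplicate protein accessions")
  if (!all(values %in% c(0, 1))) abort("all values must be 0 or 1")
  weeks <- as.integer(weeks)
  if (length(weeks) != ncol(values)) abort("one week index per column required")
  if (any(diff(weeks) <= 0)) abort("`weeks` must be strictly increasing")
  colnames(values) <- as.character(weeks)
  new_volunteer_matrix(volunteer_id, values, weeks)
}

#' @export
print.volunteer_matrix <- function(x, ...) {
  cat(sprintf(
    "<volunteer_matrix> %s: %d proteins x %d weeks (weeks %d..%d)\n",
    x$volunteer_id, nrow(x$values), ncol(x$values), min(x$weeks), max(x$weeks)
  ))
  invisible(x)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a binary presence/absence matrix
#'
#' Reads a proteins-by-weeks table of 0/1 detections for one volunteer. The
#' header row holds integer week indices; the first column holds protein
#' accessions. Cells other than 0/1 and duplicated accessions are rejected.
#'
#' @param path File path (TSV or CSV; the delimiter is auto-detected unless
#'   given).
#' @param volunteer_id Label for the volunteer; defaults to the file name.
#' @param delim Optional delimiter, `"\t"` or `","`.
#' @return A `volunteer_matrix`.
#' @export
read_presence_matrix <- function(path, volunteer_id = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% detect_delim(path)
  if (!delim %in% c("\t", ",")) abort("only tab or comma delimiters are supported")
  df <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  if (ncol(df) < 2) abort("expected a protein column plus at least one week column")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(sprintf("duplicate protein accession: %s", dup[[1]]))
  weeks <- suppressWarnings(as.integer(colnames(df)[-1]))
  if (anyNA(weeks)) abort("header must contain integer week indices")
  vals <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(matrix(!(vals %in% c("0", "1")), nrow(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-binary cell '%s' at protein %s, week %s",
      vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], weeks[bad[1, 2]]
    ))
  }
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(ids, as.character(weeks)))
  ord <- order(weeks)
  volunteer_matrix(volunteer_id %||% basename(path), m[, ord, drop = FALSE], weeks[ord])
}

#' Write a presence matrix (round-trips with [read_presence_matrix()])
#'
#' @param vm A `volunteer_matrix`.
#' @param path Output path.
#' @param delim Delimiter (tab default).
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(vm, path, delim = "\t") {
  df <- data.frame(protein = rownames(vm$values), vm$values, check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_abundance_matrix <- function(values, weeks, n_contributing = NULL, centralized = FALSE) {
  structure(
    list(values = values, weeks = as.integer(weeks),
         n_contributing = n_contributing, centralized = centralized),
    class = c(if (centralized) "differential_matrix", "abundance_matrix")
  )
}

#' Average binary detections into a mean-volunteer abundance matrix
#'
#' Unifies the protein universes of all volunteers (a protein missing from a
#' volunteer contributes an all-zero row), takes the union of sampled weeks as
#' the common grid, and averages each protein's binary detections over the
#' volunteers that have a sample at that week. Cell values are therefore the
#' fraction of contributing volunteers detecting the protein; the number of
#' contributors is recorded per cell.
#'
#' @param matrices List of `volunteer_matrix` objects.
#' @return An `abundance_matrix` with fields `values` (proteins x weeks in
#'   `[0,1]`), `weeks`, and `n_contributing`.
#' @export
build_mean_volunteer <- function(matrices) {
  if (!length(matrices)) abort("at least one volunteer matrix is required")
  stopifnot(all(vapply(matrices, inherits, logical(1), "volunteer_matrix")))
  proteins <- sort(unique(unlist(lapply(matrices, function(m) rownames(m$values)))))
  weeks <- sort(unique(unlist(lapply(matrices, function(m) m$weeks))))
  acc <- matrix(0, length(proteins), length(weeks),
                dimnames = list(proteins, as.character(weeks)))
  n_contrib <- acc
  for (m in matrices) {
    wi <- match(m$weeks, weeks)
    pi <- match(rownames(m$values), proteins)
    acc[pi, wi] <- acc[pi, wi] + m$values
    n_contrib[, wi] <- n_contrib[, wi] + 1  # all-zero rows still contribute
  }
  vals <- ifelse(n_contrib > 0, acc / n_contrib, 0)
  new_abundance_matrix(vals, weeks, n_contributing = n_contrib)
}

#' Centralize profiles into differential detection levels
#'
#' Subtracts each protein profile's mean from the profile, so positive and
#' negative values express over- and under-presence relative to the protein's
#' own average (delta-E units). Idempotent.
#'
#' @param m An `abundance_matrix` (or `differential_matrix`).
#' @return A `differential_matrix` with zero row means.
#' @export
centralize <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (ncol(m$values) < 2) abort("at least two time points are required")
  vals <- m$values - rowMeans(m$values)
  new_abundance_matrix(vals, m$weeks, n_contributing = m$n_contributing,
                       centralized = TRUE)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "<%s> %d proteins x %d weeks (weeks %d..%d)\n",
    if (x$centralized) "differential_matrix" else "abundance_matrix",
    nrow(x$values), ncol(x$values), min(x$weeks), max(x$weeks)
  ))
  invisible(x)
}

#' @export
tidy.abundance_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "week", values_to = "value") |>
    dplyr::mutate(week = as.integer(.data$week))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Members are deduplicated; empty sets are rejected. The category (BP, CC,
#' MF, tissue, custom) is taken from the description field when it matches a
#' known category, otherwise `custom`.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list with elements `sets` (named
#'   list of member character vectors) and `categories` (named character).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); cats <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("malformed GMT line %d: need name, description and >= 1 member", i))
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) abort(sprintf("empty member list at GMT line %d", i))
    sets[[parts[[1]]]] <- members
    cats[[parts[[1]]]] <- if (parts[[2]] %in% c("BP", "CC", "MF", "tissue")) parts[[2]] else "custom"
  }
  gene_set_collection(sets, cats)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set members).
#' @param categories Optional named character of categories per set.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = NULL) {
  if (!length(sets) || is.null(names(sets))) abort("`sets` must be a named list")
  if (any(lengths(sets) == 0)) abort("empty gene sets are not allowed")
  sets <- lapply(sets, unique)
  categories <- categories %||% stats::setNames(rep("custom", length(sets)), names(sets))
  structure(list(sets = sets, categories = categories[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d..%d members\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$categories[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an optional accession-to-gene mapping table
#'
#' Two-column TSV (accession, gene). Used to translate gene-symbol sets onto
#' the protein universe; unmapped proteins stay in the universe but in no set.
#'
#' @param path TSV path.
#' @return A tibble with columns `accession`, `gene`.
#' @export
read_accession_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(df) < 2) abort("mapping table needs two columns: accession, gene")
  tibble(accession = df[[1]], gene = df[[2]])
}
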