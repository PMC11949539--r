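#' Presence/absence occurrence table
#'
#' The central input object: one row per sampled unit (e.g. a host colony or
#' a habitat), a grouping label per row (host species or habitat name), and
#' one binary column per target species (1 = present, 0 = absent, `NA` =
#' not scored).  Per group/species pair, the available sample size
#' `k_MAX` is the number of rows of that group with a non-missing entry in
#' that species column.
#'
#' @param values Matrix or data frame of 0/1/`NA` entries, rows = sampled
#'   units, columns = species.
#' @param group Character vector of group labels, one per row.
#' @param species Optional character vector of species names; defaults to
#'   the column names of `values`.
#'
#' @return An object of class `"occurrence_table"` with components `group`,
#'   `species` and `values` (integer matrix).
#' @seealso [read_occurrence_csv()], [estimate_all()]
#' @examples
#' occurrence_table(cbind(spA = c(1, 0, 1), spB = c(0, 0, NA)),
#'                  group = c("host1", "host1", "host2"))
#' @export
occurrence_table <- function(values, group, species = colnames(values)) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("`values` must be a matrix or data frame",
                               call. = FALSE)
  if (nrow(values) < 1L) stop("occurrence table has zero data rows",
                              call. = FALSE)
  if (ncol(values) < 1L) stop("occurrence table has no species columns",
                              call. = FALSE)
  if (is.null(species)) species <- paste0("species", seq_len(ncol(values)))
  species <- trimws(as.character(species))
  if (anyDuplicated(species))
    stop("duplicate species column names: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  group <- trimws(as.character(group))
  if (length(group) != nrow(values))
    stop("`group` must have one label per row", call. = FALSE)
  if (any(is.na(group) | group == ""))
    stop("group labels must be non-empty strings", call. = FALSE)

  storage.mode(values) <- "double"
  rep <- validate_binary_matrix(values, species)
  if (!rep$ok) {
    msg <- apply(head(rep$issues, 5L), 1L, function(r)
      sprintf("row %s, column '%s': %s", r[["row"]], r[["column"]],
              r[["message"]]))
    stop("invalid occurrence values:\n  ", paste(msg, collapse = "\n  "),
         if (nrow(rep$issues) > 5L) sprintf("\n  (and %d more)",
                                            nrow(rep$issues) - 5L),
         call. = FALSE)
  }
  storage.mode(values) <- "integer"
  colnames(values) <- species
  structure(list(group = group, species = species, values = values),
            class = "occurrence_table")
}

#' Validate the cells of an occurrence table
#'
#' Checks that every non-missing entry is exactly 0 or 1 and returns a
#' validation report rather than failing, so that all offending cells can be
#' listed at once.
#'
#' @param values Matrix (or data frame) of candidate occurrence values.
#' @param species Optional column names used in the report.
#' @return A list of class `"validation_report"` with `ok` (logical) and
#'   `issues` (data frame with columns `row`, `column`, `message`); `ok` is
#'   `TRUE` iff `issues` has no rows.
#' @examples
#' validate_occurrence(cbind(a = c(0, 2)))
#' @export
validate_occurrence <- function(values, species = colnames(values)) {
  if (is.data.frame(values)) values <- as.matrix(values)
  suppressWarnings(storage.mode(values) <- "double")
  validate_binary_matrix(values, species)
}

validate_binary_matrix <- function(values, species) {
  bad <- which(!is.na(values) & values != 0 & values != 1, arr.ind = TRUE)
  issues <- data.frame(row = integer(), column = character(),
                       message = character(), stringsAsFactors = FALSE)
  if (nrow(bad) > 0L) {
    issues <- data.frame(
      row = as.integer(bad[, 1L]),
      column = species[bad[, 2L]],
      message = sprintf("value '%s' is not 0, 1 or empty",
                        values[bad]),
      stringsAsFactors = FALSE
    )
  }
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("Occurrence values OK\n")
  } else {
    cat(sprintf("%d invalid cell(s):\n", nrow(x$issues)))
    print(x$issues)
  }
  invisible(x)
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("Occurrence table: %d sampled units, %d species, %d group(s)\n",
              nrow(x$values), length(x$species), length(unique(x$group))))
  scored <- colSums(!is.na(x$values))
  cat("  species:", paste(sprintf("%s (%d scored)", x$species, scored),
                          collapse = ", "), "\n")
  cat("  groups: ", paste(unique(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' Read a wide-format presence/absence CSV
#'
#' Expects a header row; one column holds the group label (host species or
#' habitat, by default the first column) and every other column is a binary
#' species column with cells 0, 1 or empty (empty cells become missing).
#'
#' @param path Path to the delimited text file.
#' @param group_column Name or position of the grouping column (default 1).
#' @param delimiter Field delimiter: `","` (default), `";"` or `"\t"`.
#' @return An [occurrence_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("host,sp1", "A,1", "A,0"), f)
#' read_occurrence_csv(f)
#' @export
read_occurrence_csv <- function(path, group_column = 1L, delimiter = ",") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  delimiter <- match.arg(delimiter, c(",", ";", "\t"))
  raw <- read.csv(path, sep = delimiter, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("", "NA"))
  if (nrow(raw) == 0L) stop("input file has zero data rows", call. = FALSE)
  gi <- if (is.character(group_column)) {
    m <- match(group_column, names(raw))
    if (is.na(m)) stop("group column '", group_column, "' not found",
                       call. = FALSE)
    m
  } else as.integer(group_column)
  if (gi < 1L || gi > ncol(raw)) stop("invalid group column position",
                                      call. = FALSE)
  if (ncol(raw) < 2L) stop("no species columns besides the group column",
                           call. = FALSE)
  sp_names <- names(raw)[-gi]  # [.data.frame would deduplicate these
  vals <- as.matrix(raw[, -gi, drop = FALSE])
  colnames(vals) <- sp_names
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  # non-numeric text is as invalid as an out-of-range number; keep a marker
  num[!is.na(vals) & is.na(num)] <- -1
  occurrence_table(num, group = raw[[gi]], species = colnames(vals))
}

#' Write a tidy results CSV
#'
#' One row per group/species pair with the detected stability point,
#' prevalence estimates and the full effective parameter set.  An
#' undetermined stability point is written as `"na"`, matching the figure
#' annotation.
#'
#' @param results A [estimate_all()] scan or the data frame obtained from it
#'   via `as.data.frame()`.
#' @param path Output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_results_csv <- function(results, path) {
  df <- if (inherits(results, "stability_scan")) as.data.frame(results)
        else as.data.frame(results)
  if (nrow(df) == 0L) stop("no results to write", call. = FALSE)
  out <- df
  out$stability_point <- ifelse(is.na(df$stability_point), "na",
                                as.character(df$stability_point))
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "na")
  invisible(df)
}

#' Read back a results CSV written by [write_results_csv()]
#'
#' @param path Path to the results file.
#' @return Data frame on the results schema, `"na"` cells restored to `NA`.
#' @export
read_results_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("na", "NA"))
  df$stability_point <- as.integer(df$stability_point)
  df
}

#' Build a synthetic occurrence table with exact per-pair totals
#'
#' Fixture generator: given one row per (group, species) pair with the
#' number of scored units `k_max` and the number of presences among them,
#' assembles a wide occurrence table whose observed counts match the request
#' exactly, with row order shuffled.  Species not scored in a group are
#' missing there.
#'
#' @param spec Data frame with columns `group`, `species`, `k_max`, `ones`.
#' @param seed Optional seed for the row shuffle.
#' @return An [occurrence_table()].
#' @examples
#' make_fixture_table(data.frame(group = "H", species = "s",
#'                               k_max = 10, ones = 5))
#' @export
make_fixture_table <- function(spec, seed = NULL) {
  if (!is.data.frame(spec) || nrow(spec) == 0L)
    stop("`spec` must be a non-empty data frame", call. = FALSE)
  need <- c("group", "species", "k_max", "ones")
  if (!all(need %in% names(spec)))
    stop("`spec` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(spec[c("group", "species")]))
    stop("duplicate (group, species) entries in `spec`", call. = FALSE)
  if (any(spec$k_max < 1) || any(spec$ones < 0) ||
      any(spec$ones > spec$k_max))
    stop("`spec` requires 0 <= ones <= k_max and k_max >= 1", call. = FALSE)

  local_seed(seed, {
    groups <- unique(spec$group)
    species <- unique(spec$species)
    blocks <- lapply(groups, function(g) {
      sub <- spec[spec$group == g, , drop = FALSE]
      nr <- max(sub$k_max)
      block <- matrix(NA_real_, nr, length(species),
                      dimnames = list(NULL, species))
      for (i in seq_len(nrow(sub))) {
        col <- c(rep(1, sub$ones[i]), rep(0, sub$k_max[i] - sub$ones[i]),
                 rep(NA, nr - sub$k_max[i]))
        block[, sub$species[i]] <- sample(col)
      }
      block
    })
    values <- do.call(rbind, blocks)
    group <- rep(groups, vapply(blocks, nrow, 0L))
    occurrence_table(values, group = group, species = species)
  })
}

#' Path to the packaged synthetic coral-symbiont example
#'
#' A synthetic surrogate for a Caribbean coral survey: six host groups
#' (five coral taxa, one of them split across two depths) scored for six
#' coral-dwelling symbiont species (crabs, a barnacle, a blenny, a
#' fanworm), nine scored host--symbiont pairs in total.  Group sample sizes
#' and prevalences emulate a real survey in which one host (104 colonies)
#' was sampled sufficiently while another (35 colonies, with a sparsely
#' scored fanworm) was not.
#'
#' @return File path of the packaged CSV.
#' @examples
#' tab <- read_occurrence_csv(coral_example_path())
#' table(tab$group)
#' @export
coral_example_path <- function() {
  system.file("extdata", "coral_symbionts_synthetic.csv",
              package = "prevstab", mustWork = TRUE)
}
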