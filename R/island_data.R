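#' Create a colonist record
#'
#' One record per independent colonisation of the island by a mainland
#' species.  Five data-entry types are distinguished by `status`:
#'
#' 1. the mainland species left no extant island descendants (it may have
#'    colonised and later died out; nothing is observed);
#' 2. a non-endemic island population is present but only an upper bound on
#'    the colonisation time is known;
#' 3. a non-endemic island population is present and the colonisation time
#'    (divergence from the mainland population) is known;
#' 4. an endemic species or clade is present and the mainland relative is
#'    absent from the island;
#' 5. an endemic clade co-occurs with its re-immigrated non-endemic mainland
#'    sister species.
#'
#' All times are ages in million years (My) before present.  Branching times
#' are the ages of in-situ cladogenesis events in the island clade (crown age
#' first); they apply to statuses 4 and 5 only.
#'
#' @param label free-text identifier for the colonist (used in messages).
#' @param status integer 1-5, see Details.
#' @param colonisation_time age of colonisation in My before present; for
#'   status 2 an upper bound; absent (`NA`) for status 1, in which case the
#'   island age is the implicit bound.
#' @param branching_times numeric vector of branching ages (My before
#'   present), strictly younger than `colonisation_time`; empty for statuses
#'   1-3.
#' @param n_missing number of extant island species of this colonist that are
#'   absent from the phylogeny (they enter the likelihood through the hidden
#'   species count).
#' @param lineage_class categorical label of the mainland-pool class this
#'   species belongs to (e.g. `"DF-type"` / `"non-DF-type"`).
#' @param max_age logical; `TRUE` when `colonisation_time` is an upper bound
#'   rather than a point estimate.  Defaults to `TRUE` for status 2 and
#'   `FALSE` otherwise.
#' @return an object of class `colonist_record`.
#' @seealso [island_dataset()]
#' @export
#' @examples
#' colonist_record("warbler", status = 4, colonisation_time = 2.1,
#'                 branching_times = c(1.2, 0.4))
colonist_record <- function(label, status, colonisation_time = NA_real_,
                            branching_times = numeric(), n_missing = 0L,
                            lineage_class = "all",
                            max_age = identical(as.integer(status), 2L)) {
  status <- as.integer(status)
  rec <- structure(
    list(label = as.character(label), status = status,
         colonisation_time = as.numeric(colonisation_time),
         branching_times = sort(as.numeric(branching_times),
                                decreasing = TRUE),
         n_missing = as.integer(n_missing),
         lineage_class = as.character(lineage_class),
         max_age = isTRUE(max_age)),
    class = "colonist_record")
  validate_colonist_record(rec)
  rec
}

validate_colonist_record <- function(rec) {
  lab <- rec$label
  fail <- function(msg) stop("colonist record '", lab, "': ", msg,
                             call. = FALSE)
  if (!rec$status %in% 1:5) fail("status must be an integer in 1..5")
  if (rec$n_missing < 0) fail("n_missing must be >= 0")
  if (rec$status == 1L) {
    if (length(rec$branching_times)) fail("status 1 has no branching times")
    return(invisible(TRUE))
  }
  if (!is.finite(rec$colonisation_time) || rec$colonisation_time <= 0)
    fail("colonisation_time must be a positive age for statuses 2-5")
  if (rec$status %in% 2:3) {
    if (length(rec$branching_times))
      fail("statuses 2-3 are single non-endemic populations without branching times")
  }
  if (length(rec$branching_times)) {
    bt <- rec$branching_times
    if (any(bt <= 0)) fail("branching times must be positive ages")
    if (max(bt) >= rec$colonisation_time)
      fail(sprintf("branching time %g is not younger than colonisation time %g",
                   max(bt), rec$colonisation_time))
    if (anyDuplicated(bt))
      fail("branching times must be strictly decreasing when sorted by age")
  }
  invisible(TRUE)
}

#' Number of phylogeny lineages implied by a record
#'
#' Statuses 2-3 contribute one non-endemic lineage; statuses 4-5 contribute
#' one lineage per branching time plus one; status 1 contributes none.
#'
#' @param rec a [colonist_record()].
#' @return integer count of lineages in the phylogeny at the present.
#' @export
record_k <- function(rec) {
  switch(rec$status, 0L, 1L, 1L,
         length(rec$branching_times) + 1L,
         length(rec$branching_times) + 1L)
}

#' Total extant island species implied by a record
#'
#' Phylogeny lineages plus missing species plus, for status 5, the
#' co-occurring non-endemic population.
#'
#' @param rec a [colonist_record()].
#' @return integer species count.
#' @export
record_n_species <- function(rec) {
  record_k(rec) + rec$n_missing + as.integer(rec$status == 5L)
}

#' Assemble an island community dataset
#'
#' Bundles the island age, the mainland pool description and the list of
#' colonist records that the likelihood consumes.
#'
#' @param island_age age of the island (My): the window over which assembly
#'   has been possible.
#' @param M total number of species in the mainland pool.
#' @param colonists list of [colonist_record()] objects, one per independent
#'   colonisation.
#' @param class_fractions named numeric vector mapping each lineage class to
#'   its fraction of the mainland pool; must sum to 1.
#' @return an object of class `island_dataset`.
#' @export
#' @examples
#' d <- island_dataset(island_age = 4, M = 1000,
#'   colonists = list(colonist_record("finch-like", 4, 1.5, c(0.8, 0.3))),
#'   class_fractions = c(all = 1))
#' d
island_dataset <- function(island_age, M, colonists = list(),
                           class_fractions = c(all = 1)) {
  ds <- structure(
    list(island_age = as.numeric(island_age), M = as.numeric(M),
         class_fractions = unlist(class_fractions),
         colonists = colonists),
    class = "island_dataset")
  validate_island_dataset(ds)
  ds
}

#' Validate an island dataset
#'
#' Checks every invariant of the data model: record-level consistency,
#' ages within the island age, class fractions summing to one, and class
#' counts not exceeding the class's share of the mainland pool.
#'
#' @param ds an [island_dataset()].
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_island_dataset <- function(ds) {
  if (!is.finite(ds$island_age) || ds$island_age <= 0)
    stop("island_age must be positive", call. = FALSE)
  if (!is.finite(ds$M) || ds$M <= 0)
    stop("mainland pool size M must be positive", call. = FALSE)
  cf <- ds$class_fractions
  if (is.null(names(cf)) || any(!nzchar(names(cf))))
    stop("class_fractions must be named", call. = FALSE)
  if (abs(sum(cf) - 1) > 1e-8)
    stop("class fractions must sum to 1 (got ", sum(cf), ")", call. = FALSE)
  for (rec in ds$colonists) {
    if (!inherits(rec, "colonist_record"))
      stop("colonists must be colonist_record objects", call. = FALSE)
    validate_colonist_record(rec)
    if (is.finite(rec$colonisation_time) &&
        rec$colonisation_time > ds$island_age + 1e-9)
      stop("colonist record '", rec$label, "': colonisation time ",
           rec$colonisation_time, " exceeds island age ", ds$island_age,
           call. = FALSE)
    if (!rec$lineage_class %in% names(cf) || cf[rec$lineage_class] <= 0)
      stop("colonist record '", rec$label, "': lineage class '",
           rec$lineage_class, "' has no positive mainland fraction",
           call. = FALSE)
  }
  cls <- vapply(ds$colonists, function(r) r$lineage_class, character(1))
  for (cl in names(cf)) {
    n_cl <- sum(cls == cl)
    if (n_cl > ds$M * cf[[cl]] + 1e-9)
      stop("class '", cl, "' has ", n_cl,
           " observed colonists but a mainland share of only ",
           ds$M * cf[[cl]], " species", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.island_dataset <- function(x, ...) {
  cat("island dataset: age", x$island_age, "My, mainland pool M =", x$M, "\n")
  cat(" classes:",
      paste(sprintf("%s (%.3f)", names(x$class_fractions), x$class_fractions),
            collapse = ", "), "\n")
  cat(" ", length(x$colonists), "colonisation(s),",
      sum(vapply(x$colonists, record_n_species, integer(1))),
      "extant island species\n")
  for (rec in x$colonists)
    cat(sprintf("  - %-18s status %d  t_c %s%s  clade %d  [%s]\n",
                rec$label, rec$status,
                ifelse(is.finite(rec$colonisation_time),
                       format(rec$colonisation_time, digits = 4), "-"),
                ifelse(rec$max_age, " (max)", ""),
                record_n_species(rec), rec$lineage_class))
  invisible(x)
}

record_to_row <- function(rec) {
  # times go through %.17g so that the text round-trip is bit-exact
  data.frame(label = rec$label, status = rec$status,
             colonisation_time = sprintf("%.17g", rec$colonisation_time),
             branching_times = paste(sprintf("%.17g", rec$branching_times),
                                     collapse = ";"),
             n_missing = rec$n_missing, lineage_class = rec$lineage_class,
             max_age = rec$max_age, stringsAsFactors = FALSE)
}

row_to_record <- function(row) {
  bt <- if (is.na(row$branching_times) || !nzchar(row$branching_times))
    numeric() else as.numeric(strsplit(row$branching_times, ";")[[1]])
  tc <- suppressWarnings(as.numeric(row$colonisation_time))
  colonist_record(row$label, row$status, tc, bt,
                  row$n_missing, row$lineage_class, isTRUE(row$max_age))
}

#' Read an island dataset from file
#'
#' Two dialects are supported.  The JSON dialect mirrors the data model
#' (nested records; see `inst/extdata/dataset-schema.json`).  The TSV dialect
#' is a flat spreadsheet export: one row per colonist plus `# key value`
#' header lines for island age, pool size and class fractions.
#'
#' @param path file path.
#' @param format `"json"` or `"tsv"`; the default guesses from the file
#'   extension.
#' @return a validated [island_dataset()].
#' @export
read_island_dataset <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "json"
  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error in ", path, ": ", conditionMessage(e),
                           call. = FALSE))
    need <- c("island_age", "M", "class_fractions", "colonists")
    miss <- setdiff(need, names(obj))
    if (length(miss))
      stop("parse error in ", path, ": missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    colonists <- lapply(obj$colonists, function(cj) {
      lab <- if (is.null(cj$label)) "<unnamed>" else cj$label
      if (is.null(cj$status))
        stop("parse error in record '", lab, "': no status", call. = FALSE)
      colonist_record(
        lab, cj$status,
        if (is.null(cj$colonisation_time)) NA_real_ else cj$colonisation_time,
        if (is.null(cj$branching_times)) numeric()
        else unlist(cj$branching_times),
        if (is.null(cj$n_missing)) 0L else cj$n_missing,
        if (is.null(cj$lineage_class)) "all" else cj$lineage_class,
        if (is.null(cj$max_age)) identical(as.integer(cj$status), 2L)
        else isTRUE(cj$max_age))
    })
    island_dataset(obj$island_age, obj$M, colonists,
                   unlist(obj$class_fractions))
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    kv <- strsplit(sub("^#\\s*", "", hdr), "\t")
    meta <- setNames(lapply(kv, function(x) x[-1]),
                     vapply(kv, `[`, character(1), 1))
    if (is.null(meta$island_age) || is.null(meta$M))
      stop("parse error in ", path,
           ": TSV header must carry island_age and M", call. = FALSE)
    cf_names <- strsplit(meta$class_names[1], ";")[[1]]
    cf_vals <- as.numeric(strsplit(meta$class_fractions[1], ";")[[1]])
    body <- lines[!grepl("^#", lines)]
    colonists <- list()
    if (length(body) > 1) {
      tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                        stringsAsFactors = FALSE)
      tab$branching_times <- as.character(tab$branching_times)
      colonists <- lapply(seq_len(nrow(tab)),
                          function(i) row_to_record(tab[i, ]))
    }
    island_dataset(as.numeric(meta$island_age[1]), as.numeric(meta$M[1]),
                   colonists, setNames(cf_vals, cf_names))
  }
}

#' Write an island dataset to file
#'
#' Inverse of [read_island_dataset()]: `read(write(d))` reproduces `d` in
#' both formats.
#'
#' @param ds a validated [island_dataset()].
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_island_dataset <- function(ds, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  validate_island_dataset(ds)
  if (format == "json") {
    obj <- list(
      island_age = ds$island_age, M = ds$M,
      class_fractions = as.list(ds$class_fractions),
      colonists = lapply(ds$colonists, function(r) {
        list(label = r$label, status = r$status,
             colonisation_time = if (is.finite(r$colonisation_time))
               r$colonisation_time else NULL,
             branching_times = as.list(r$branching_times),
             n_missing = r$n_missing, lineage_class = r$lineage_class,
             max_age = r$max_age)
      }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# island_age\t", format(ds$island_age, digits = 17)),
                 paste0("# M\t", format(ds$M, digits = 17)),
                 paste0("# class_names\t",
                        paste(names(ds$class_fractions), collapse = ";")),
                 paste0("# class_fractions\t",
                        paste(format(ds$class_fractions, digits = 17),
                              collapse = ";"))), con)
    rows <- do.call(rbind, lapply(ds$colonists, record_to_row))
    if (is.null(rows))
      rows <- record_to_row(colonist_record("x", 1))[0, ]
    suppressWarnings(write.table(rows, con, sep = "\t", row.names = FALSE,
                                 quote = FALSE))
  }
  invisible(path)
}
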