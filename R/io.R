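#' Describe the on-disk layout of a replicate genotype table
#'
#' Replicate tables are long ("tidy") delimited text: one row per
#' sample x replicate x locus with two allele calls, or a status token.
#' Status tokens are written in the first allele column (the second may
#' repeat the token or be empty).
#'
#' @param delimiter Field delimiter (default tab).
#' @param missing_token,contamination_token,disputed_token Tokens marking
#'   non-called statuses; must be mutually distinct.
#' @param col_sample,col_replicate,col_locus,col_allele_1,col_allele_2 Column
#'   names; must be unique.
#' @return A `replicate_dialect` list.
#' @export
replicate_dialect <- function(delimiter = "\t",
                              missing_token = "NA",
                              contamination_token = "CONT",
                              disputed_token = "DISPUTED",
                              col_sample = "sample_id",
                              col_replicate = "replicate",
                              col_locus = "locus",
                              col_allele_1 = "allele_1",
                              col_allele_2 = "allele_2") {
  tokens <- c(missing = missing_token, contaminated = contamination_token,
              disputed = disputed_token)
  if (anyDuplicated(tokens)) stop("status tokens must be mutually distinct")
  cols <- c(col_sample, col_replicate, col_locus, col_allele_1, col_allele_2)
  if (anyDuplicated(cols)) stop("column names must be unique")
  structure(list(delimiter = delimiter, tokens = tokens,
                 cols = list(sample = col_sample, replicate = col_replicate,
                             locus = col_locus, allele_1 = col_allele_1,
                             allele_2 = col_allele_2)),
            class = "replicate_dialect")
}

#' Read a replicate-level genotype table
#'
#' Parses a delimited file of per-replicate genotype calls into the
#' canonical replicate data frame used throughout the package. Every locus
#' of the panel is materialised for every (sample, replicate): loci absent
#' from the file become `missing` calls.
#'
#' @param path File to read.
#' @param panel The active [locus_panel]; rows naming loci outside the panel
#'   are an error.
#' @param dialect A [replicate_dialect].
#' @return A list with `replicates` (data frame: `sample_id`, `replicate`,
#'   `locus`, `allele_1`, `allele_2`, `status`) and `report` (row counts by
#'   parsed status; counts sum to the number of data rows in the file).
#' @export
read_replicate_table <- function(path, panel, dialect = replicate_dialect()) {
  stopifnot(file.exists(path), inherits(panel, "locus_panel"))
  raw <- utils::read.delim(path, sep = dialect$delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, strip.white = TRUE)
  need <- unlist(dialect$cols)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  df <- data.frame(
    sample_id = raw[[dialect$cols$sample]],
    replicate = as.integer(raw[[dialect$cols$replicate]]),
    locus = raw[[dialect$cols$locus]],
    a1_raw = raw[[dialect$cols$allele_1]],
    a2_raw = raw[[dialect$cols$allele_2]],
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate index must be an integer >= 1")
  }
  unknown <- !(df$locus %in% panel$name)
  if (any(unknown)) {
    stop("unknown loci not in panel: ",
         paste(unique(df$locus[unknown]), collapse = ", "),
         " (rows ", paste(utils::head(which(unknown), 10), collapse = ", "),
         ")")
  }

  status <- rep("called", nrow(df))
  for (st in names(dialect$tokens)) {
    status[df$a1_raw == dialect$tokens[[st]]] <- st
  }
  tokenish <- df$a1_raw %in% dialect$tokens
  a2_empty <- df$a2_raw == "" | df$a2_raw %in% dialect$tokens
  if (any(tokenish & !a2_empty)) {
    stop("status token in first allele column but a second allele given ",
         "(rows ", paste(utils::head(which(tokenish & !a2_empty), 10),
                         collapse = ", "), ")")
  }
  called <- status == "called"
  a1 <- suppressWarnings(as.integer(df$a1_raw))
  a2 <- suppressWarnings(as.integer(df$a2_raw))
  bad_num <- called & (is.na(a1) | df$a1_raw != as.character(a1))
  if (any(bad_num)) {
    stop("non-integer allele labels (rows ",
         paste(utils::head(which(bad_num), 10), collapse = ", "),
         "); allele labels must be fragment sizes in bp")
  }
  half <- called & (df$a2_raw == "" | is.na(a2))
  if (any(half)) {
    stop("allele_1 present without allele_2 (rows ",
         paste(utils::head(which(half), 10), collapse = ", "),
         "); homozygotes must be written as an equal pair")
  }
  bad_num2 <- called & !half & df$a2_raw != as.character(a2)
  if (any(bad_num2)) {
    stop("non-integer allele labels (rows ",
         paste(utils::head(which(bad_num2), 10), collapse = ", "), ")")
  }

  out <- data.frame(
    sample_id = df$sample_id, replicate = df$replicate, locus = df$locus,
    allele_1 = ifelse(called, pmin(a1, a2), NA_integer_),
    allele_2 = ifelse(called, pmax(a1, a2), NA_integer_),
    status = status, stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("sample_id", "replicate", "locus")])
  if (any(dup)) {
    stop("duplicated (sample, replicate, locus) rows: ",
         paste(utils::head(which(dup), 10), collapse = ", "))
  }
  report <- as.list(table(factor(status, levels = .call_statuses)))
  report$n_rows <- nrow(df)

  list(replicates = complete_replicates(out, panel), report = report)
}

#' Fill in panel loci absent from a replicate table as missing calls
#'
#' @param replicates Replicate data frame (`sample_id`, `replicate`, `locus`,
#'   `allele_1`, `allele_2`, `status`).
#' @param panel A [locus_panel].
#' @return The completed replicate data frame, ordered by sample, replicate,
#'   panel locus order.
#' @export
complete_replicates <- function(replicates, panel) {
  keys <- unique(replicates[, c("sample_id", "replicate")])
  full <- merge(merge(keys, data.frame(locus = panel$name)), replicates,
                by = c("sample_id", "replicate", "locus"), all.x = TRUE)
  full$status[is.na(full$status)] <- "missing"
  ord <- order(full$sample_id, full$replicate,
               match(full$locus, panel$name))
  full <- full[ord, c("sample_id", "replicate", "locus",
                      "allele_1", "allele_2", "status")]
  rownames(full) <- NULL
  full
}

#' Write a replicate table
#'
#' Inverse of [read_replicate_table()]; round-trips statuses and alleles.
#' @param replicates Canonical replicate data frame.
#' @param path Output file.
#' @param dialect A [replicate_dialect].
#' @return `path`, invisibly.
#' @export
write_replicate_table <- function(replicates, path,
                                  dialect = replicate_dialect()) {
  a1 <- as.character(replicates$allele_1)
  a2 <- as.character(replicates$allele_2)
  for (st in names(dialect$tokens)) {
    sel <- replicates$status == st
    a1[sel] <- dialect$tokens[[st]]
    a2[sel] <- dialect$tokens[[st]]
  }
  out <- data.frame(replicates$sample_id, replicates$replicate,
                    replicates$locus, a1, a2)
  names(out) <- unlist(dialect$cols)
  utils::write.table(out, path, sep = dialect$delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a wide replicate layout to the canonical long layout
#'
#' Convenience for spreadsheets with one row per sample x replicate and a
#' pair of columns per locus named `<locus>.1` / `<locus>.2`.
#'
#' @param wide Data frame with columns `sample_id`, `replicate`, then locus
#'   pairs.
#' @param panel A [locus_panel].
#' @param dialect A [replicate_dialect] (for status tokens).
#' @return Canonical replicate data frame.
#' @export
replicates_from_wide <- function(wide, panel, dialect = replicate_dialect()) {
  stopifnot(all(c("sample_id", "replicate") %in% names(wide)))
  pieces <- lapply(panel$name, function(loc) {
    c1 <- paste0(loc, ".1"); c2 <- paste0(loc, ".2")
    if (!c1 %in% names(wide)) return(NULL)
    data.frame(sample_id = wide$sample_id,
               replicate = as.integer(wide$replicate),
               locus = loc, a1 = as.character(wide[[c1]]),
               a2 = as.character(wide[[c2]]), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  status <- rep("called", nrow(long))
  for (st in names(dialect$tokens)) {
    status[long$a1 == dialect$tokens[[st]]] <- st
  }
  called <- status == "called"
  a1 <- suppressWarnings(as.integer(long$a1))
  a2 <- suppressWarnings(as.integer(long$a2))
  if (any(called & (is.na(a1) | is.na(a2)))) {
    stop("non-integer allele labels in wide table")
  }
  out <- data.frame(sample_id = long$sample_id, replicate = long$replicate,
                    locus = long$locus,
                    allele_1 = ifelse(called, pmin(a1, a2), NA_integer_),
                    allele_2 = ifelse(called, pmax(a1, a2), NA_integer_),
                    status = status, stringsAsFactors = FALSE)
  complete_replicates(out, panel)
}

#' Read sample metadata
#'
#' @param path Delimited file with columns `sample_id`, `sample_type`,
#'   `collection_date` (ISO-8601 `YYYY-MM-DD`), `location`.
#' @param delimiter Field delimiter.
#' @return Data frame with parsed `Date` column; unique sample ids enforced.
#' @export
read_sample_meta <- function(path, delimiter = "\t") {
  meta <- utils::read.delim(path, sep = delimiter, colClasses = "character",
                            strip.white = TRUE)
  need <- c("sample_id", "sample_type", "collection_date", "location")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  types <- c("scat", "urine", "hair", "tissue", "blood")
  bad <- !(meta$sample_type %in% types)
  if (any(bad)) {
    stop("unknown sample_type: ",
         paste(unique(meta$sample_type[bad]), collapse = ", "))
  }
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", meta$collection_date)
  if (!all(iso)) stop("collection_date must be ISO-8601 (YYYY-MM-DD)")
  meta$collection_date <- as.Date(meta$collection_date)
  if (anyNA(meta$collection_date)) stop("unparseable collection_date")
  meta
}

#' Write individual consensus genotypes as a Genepop file
#'
#' Standard Genepop layout: a title line, one locus name per line, a `Pop`
#' line, then one genotype row per individual using 3-digit allele coding
#' (missing locus = `000000`). Interoperates with the classic microsatellite
#' population-genetics tool chain.
#'
#' @param individuals An `individual_set` (see [cluster_individuals()]) or a
#'   long consensus data frame with columns `individual_id`, `locus`,
#'   `allele_1`, `allele_2`, `status`.
#' @param panel A [locus_panel]; autosomal loci are exported in panel order.
#' @param path Output file.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(individuals, panel, path,
                          title = "nivgeno individual consensus genotypes") {
  cons <- if (inherits(individuals, "individual_set")) {
    individuals$consensus
  } else individuals
  stopifnot(is.data.frame(cons),
            all(c("individual_id", "locus", "status") %in% names(cons)))
  loci <- autosomal_loci(panel)
  ids <- sort(unique(cons$individual_id))
  if (length(ids) < 1L) stop("need at least one individual")
  called <- cons$status == "called"
  if (any(called & (cons$allele_1 > 999 | cons$allele_1 < 1 |
                    cons$allele_2 > 999 | cons$allele_2 < 1))) {
    stop("allele size not encodable in 3 digits")
  }
  code <- function(a) sprintf("%03d", a)
  key <- paste(cons$individual_id, cons$locus)
  a1 <- cons$allele_1[match(paste(rep(ids, each = length(loci)),
                                  rep(loci, length(ids))), key)]
  a2 <- cons$allele_2[match(paste(rep(ids, each = length(loci)),
                                  rep(loci, length(ids))), key)]
  st <- cons$status[match(paste(rep(ids, each = length(loci)),
                                rep(loci, length(ids))), key)]
  ok <- !is.na(st) & st == "called"
  field <- ifelse(ok, paste0(code(ifelse(ok, a1, 0L)),
                             code(ifelse(ok, a2, 0L))), "000000")
  gmat <- matrix(field, nrow = length(ids), byrow = TRUE)
  lines <- c(title, loci, "Pop",
             paste0(ids, " ,  ", apply(gmat, 1, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Genepop file (single population, 3-digit coding)
#'
#' Minimal reader covering the dialect written by [write_genepop()]: used for
#' round-trip verification and for importing individual genotype sets
#' produced elsewhere.
#'
#' @param path Genepop file.
#' @return Long data frame `individual_id`, `locus`, `allele_1`, `allele_2`,
#'   `status`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_at <- which(toupper(trimws(lines)) == "POP")[1]
  if (is.na(pop_at) || pop_at < 3L) stop("not a Genepop file")
  loci <- trimws(lines[2:(pop_at - 1)])
  if (any(grepl(",", loci))) {
    loci <- trimws(unlist(strsplit(loci, ",")))
  }
  rows <- lapply(lines[(pop_at + 1):length(lines)], function(ln) {
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed genotype row: ", ln)
    id <- trimws(parts[1])
    fields <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(fields) != length(loci)) {
      stop("genotype row has ", length(fields), " fields for ",
           length(loci), " loci: ", id)
    }
    a1 <- as.integer(substr(fields, 1, 3))
    a2 <- as.integer(substr(fields, 4, 6))
    data.frame(individual_id = id, locus = loci,
               allele_1 = ifelse(a1 == 0L, NA_integer_, pmin(a1, a2)),
               allele_2 = ifelse(a1 == 0L, NA_integer_, pmax(a1, a2)),
               status = ifelse(a1 == 0L | a2 == 0L, "missing", "called"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a mitotype reference panel from FASTA
#'
#' Headers must be `name|specificity` with specificity one of `wolf`
#' (haplotype specific to gray wolves), `shared` (shared between domestic dog
#' and gray wolf, assignable only to Canis sp.), or `other` (non-target
#' species). Sequences are uppercased.
#'
#' @param fasta_path FASTA file.
#' @return Data frame `name`, `specificity`, `sequence`.
#' @export
read_haplotype_panel <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed FASTA header (expected 'name|specificity'): ",
         paste(headers[lengths(parts) != 2L], collapse = ", "))
  }
  name <- trimws(vapply(parts, `[`, "", 1))
  spec <- trimws(vapply(parts, `[`, "", 2))
  bad <- !(spec %in% c("wolf", "shared", "other"))
  if (any(bad)) {
    stop("unknown specificity flag: ", paste(unique(spec[bad]), collapse = ", "))
  }
  if (anyDuplicated(name)) {
    stop("duplicate mitotype names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  sequence <- toupper(as.character(seqs))
  if (any(nchar(sequence) == 0L)) stop("empty reference sequence")
  if (any(grepl("[^ACGTN]", sequence))) {
    stop("reference sequences must be over the alphabet A,C,G,T,N")
  }
  data.frame(name = name, specificity = spec, sequence = sequence,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a sample consensus table
#'
#' One row per sample x locus (status, alleles, per-locus quality score),
#' followed by a per-sample summary table written alongside as
#' `<path>.samples`.
#'
#' @param sc A `sample_consensus` object.
#' @param path Output file for the call-level table.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_consensus_table <- function(sc, path, delimiter = "\t") {
  stopifnot(inherits(sc, "sample_consensus"))
  utils::write.table(sc$calls, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sc$samples, paste0(path, ".samples"), sep = delimiter,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
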