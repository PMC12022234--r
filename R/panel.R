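#' Define a microsatellite locus panel
#'
#' A locus panel describes the marker set a monitoring programme genotypes:
#' a list of autosomal microsatellites plus (optionally) one sex marker
#' (amelogenin, heterozygous in male canids, homozygous in females).
#'
#' @param name Character vector of unique locus names.
#' @param multiplex_id Integer vector (values 1 or 2) giving the PCR multiplex
#'   each locus belongs to. Recycled if length 1.
#' @param size_min,size_max Integer vectors, the expected allele size range in
#'   base pairs (`size_min < size_max` per locus). Recycled if length 1.
#' @param is_sex_marker Logical vector flagging the sex marker; at most one
#'   locus may be flagged.
#'
#' @return An object of class `locus_panel`: a data frame with one row per
#'   locus and columns `name`, `multiplex_id`, `size_min`, `size_max`,
#'   `is_sex_marker`.
#' @examples
#' locus_panel(c("FH2096", "AHT103", "AMEL"),
#'             multiplex_id = c(1, 1, 2),
#'             size_min = 90, size_max = 300,
#'             is_sex_marker = c(FALSE, FALSE, TRUE))
#' @export
locus_panel <- function(name, multiplex_id = 1L, size_min = 80L,
                        size_max = 400L, is_sex_marker = FALSE) {
  name <- as.character(name)
  n <- length(name)
  if (n < 1L) stop("a panel needs at least one locus")
  if (anyDuplicated(name)) {
    stop("duplicate locus names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  panel <- data.frame(
    name = name,
    multiplex_id = as.integer(rep_len(multiplex_id, n)),
    size_min = as.integer(rep_len(size_min, n)),
    size_max = as.integer(rep_len(size_max, n)),
    is_sex_marker = rep_len(as.logical(is_sex_marker), n),
    stringsAsFactors = FALSE
  )
  if (!all(panel$multiplex_id %in% c(1L, 2L))) {
    stop("multiplex_id must be 1 or 2")
  }
  if (any(panel$size_min >= panel$size_max)) {
    stop("allele size range must have min < max")
  }
  if (sum(panel$is_sex_marker) > 1L) {
    stop("at most one locus may be flagged as the sex marker")
  }
  class(panel) <- c("locus_panel", "data.frame")
  panel
}

#' Default gray wolf monitoring panel
#'
#' The 22 autosomal microsatellites routinely used for gray wolf monitoring
#' in Europe (11 of them informative for dog-wolf hybridization), plus the
#' amelogenin sex marker, split over two multiplexes. Allele size ranges are
#' illustrative lattice bounds for simulation; real programmes calibrate them
#' per sequencer run.
#'
#' @return A [locus_panel] with 23 rows (22 autosomal + sex marker).
#' @export
default_wolf_panel <- function() {
  loci <- c("AHT103", "AHT111", "AHTk211", "FH2096", "CPH02", "FH2088",
            "C09.173", "CPH05", "FH2004", "CFX30371", "CXX279", "C09.250",
            "FH2161", "FH2140", "INU030", "FH2137", "FH2054", "C27.442",
            "Dbar1", "REN162C04", "PEZ17", "FH2010")
  locus_panel(
    name = c(loci, "AMEL"),
    multiplex_id = c(rep(1L, 11), rep(2L, 11), 2L),
    size_min = 100L,
    size_max = 400L,
    is_sex_marker = c(rep(FALSE, 22), TRUE)
  )
}

#' Autosomal loci of a panel
#'
#' @param panel A [locus_panel].
#' @return Character vector of autosomal locus names (sex marker excluded).
#' @export
autosomal_loci <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  panel$name[!panel$is_sex_marker]
}

#' Sex marker of a panel
#'
#' @param panel A [locus_panel].
#' @return The sex-marker locus name, or `NA_character_` if the panel has none.
#' @export
sex_marker <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  if (!any(panel$is_sex_marker)) return(NA_character_)
  panel$name[panel$is_sex_marker]
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("<locus_panel> ", sum(!x$is_sex_marker), " autosomal loci",
      if (any(x$is_sex_marker))
        paste0(" + sex marker (", x$name[x$is_sex_marker], ")"),
      "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
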