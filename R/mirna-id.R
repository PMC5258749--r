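#' Parse miRBase-style miRNA identifiers
#'
#' Understands identifiers of the form
#' `[species-]miR<family>[letter...][-5p|-3p]`, e.g. `aly-miR156g-5p`,
#' `miR156a`, `miR1436`. The species prefix and letter variant are optional;
#' the integer family number is mandatory.
#'
#' @param ids Character vector of identifiers.
#' @return A tibble with columns `mirna_id`, `species`, `family`
#'   (e.g. `"miR156"`), `family_number` (integer), `letter`, `arm`
#'   (`"5p"`, `"3p"` or `NA`).
#' @export
#' @examples
#' parse_mirna_id(c("aly-miR156g-5p", "miR1436", "tae-miR9672a-3p"))
parse_mirna_id <- function(ids) {
  rx <- "^(?:([A-Za-z]+)-)?[Mm][Ii][Rr](\\d+)([a-z]*)(?:-([35]p))?$"
  m <- stringr::str_match(ids, rx)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop("unparseable miRNA id: ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    mirna_id = ids,
    species = m[, 2],
    family_number = as.integer(m[, 3]),
    family = paste0("miR", m[, 3]),
    letter = dplyr::na_if(m[, 4], ""),
    arm = m[, 5]
  )
}

#' Assign a name to a newly predicted miRNA
#'
#' Applies the arm-aware renaming rules: (1) the homolog carries an arm
#' suffix matching the detected arm - keep family plus that suffix;
#' (2) the homolog carries no suffix - family plus the detected arm;
#' (3) the homolog's suffix is the opposite arm - bare family name.
#' Letter variants of the homolog are always stripped.
#'
#' @param homolog_id Character vector of reference miRNA ids.
#' @param detected_arm `"5p"` or `"3p"` per element, the hairpin arm the new
#'   mature was found on.
#' @return Character vector of assigned names (e.g. `"miR156-3p"`).
#' @export
#' @examples
#' assign_mirna_name("miR156a-3p", "3p") # rule 1 -> "miR156-3p"
#' assign_mirna_name("miR156a", "3p")    # rule 2 -> "miR156-3p"
#' assign_mirna_name("miR156a-3p", "5p") # rule 3 -> "miR156"
assign_mirna_name <- function(homolog_id, detected_arm) {
  stopifnot(all(detected_arm %in% c("5p", "3p")))
  p <- parse_mirna_id(homolog_id)
  dplyr::case_when(
    is.na(p$arm)            ~ paste0(p$family, "-", detected_arm),
    p$arm == detected_arm   ~ paste0(p$family, "-", detected_arm),
    TRUE                    ~ p$family
  )
}
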