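# The printed catalog of the 33 quadratic trimolecular (2,4,2) networks
# admitting a Bogdanov-Takens bifurcation, in catalog order, together with
# the printed supercritical / vertical / subcritical split.  Used as the
# reference the computed BT census is checked against.

#' Catalog of the 33 Bogdanov-Takens networks
#'
#' @return data.frame with columns `id`, `reactions` (canonical reaction
#'   string) and `type` (`supercritical` for 1-8, `vertical` for 9-10,
#'   `subcritical` for 11-33).
#' @export
bt_catalog <- function() {
  reactions <- c(
    "2X > 3X; X+Y > 2Y; Y > 0; 0 > Y",
    "2X > 3X; X+Y > 3Y; Y > 0; 0 > Y",
    "2X > 3X; X+Y > 2Y; Y > 0; X > Y",
    "2X > 3X; X+Y > 3Y; Y > 0; X > Y",
    "2X > 3X; X+Y > 2Y; Y > 0; X > 2Y",
    "2X > 3X; X+Y > 3Y; Y > 0; X > 2Y",
    "2X > 3X; X+Y > 2Y; Y > 0; X > 3Y",
    "2X > 3X; X+Y > 3Y; Y > 0; X > 3Y",
    "2X > 3X; X+Y > 2X; 0 > Y; X > 0",
    "2X > 3X; X+Y > 3X; 0 > Y; X > 0",
    "2X > 3X; X+Y > 2X; 0 > X+2Y; X > 0",
    "2X > 3X; X+Y > 3X; 0 > X+2Y; X > 0",
    "2X > 3X; X+Y > 2X; 0 > X+Y; X > 0",
    "2X > 3X; X+Y > 3X; 0 > X+Y; X > 0",
    "2X > 3X; X+Y > 2X; 0 > 2X+Y; X > 0",
    "2X > 3X; X+Y > 3X; 0 > 2X+Y; X > 0",
    "2X > 3X; X+Y > X; Y > X+2Y; X > Y",
    "2X > 3X; X+Y > X; Y > X+2Y; X > 2Y",
    "2X > 3X; X+Y > X; Y > X+2Y; X > 3Y",
    "2X > 3X; X+Y > 0; Y > 2X; X > 2Y",
    "2X > 3X; X+Y > 0; Y > 3X; X > 2Y",
    "2X > 3X; X+Y > 0; Y > X; X > 3Y",
    "2X > 3X; X+Y > 0; Y > 2X; X > 3Y",
    "2X > 3X; X+Y > 0; Y > 3X; X > 3Y",
    "2X > 3X; X+Y > 0; Y > X; X > X+Y",
    "2X > 3X; X+Y > 0; Y > 2X; X > X+Y",
    "2X > 3X; X+Y > 0; Y > 3X; X > X+Y",
    "2X > 3X; X+Y > Y; 2Y > 0; X > 2X+Y",
    "2X > 3X; X+Y > Y; 2Y > X; X > 2X+Y",
    "2X > 3X; X+Y > Y; 2Y > 2X; X > 2X+Y",
    "2X > 3X; X+Y > Y; 2Y > 3X; X > 2X+Y",
    "2X > 3X; X+Y > Y; 2Y > 2X+Y; X > 2X+Y",
    "2X > 3X; X+Y > 2Y; 2Y > 0; 0 > X+2Y")
  data.frame(
    id = seq_len(33),
    reactions = reactions,
    type = c(rep("supercritical", 8), rep("vertical", 2), rep("subcritical", 23)),
    stringsAsFactors = FALSE)
}

#' Diagonally equivalent pairs within the Bogdanov-Takens catalog
#' @return list of integer pairs (catalog ids).
#' @export
bt_catalog_diagonal_pairs <- function() {
  list(c(1, 2), c(3, 6), c(9, 10), c(11, 14), c(13, 16))
}
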