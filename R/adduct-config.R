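# Adduct list configuration files.

#' Read an adduct list from a text file
#'
#' One adduct per line (`+X` / `-X` syntax); blank lines and `#` comments are
#' ignored. Used to override the shipped decoy universe
#' ([default_decoy_adducts()], mirrored at
#' `system.file("extdata", "decoy_adducts.txt", package = "msiannot")`) or to
#' configure target adducts.
#'
#' @param path text file path.
#' @return Character vector of adduct strings (validated by parsing).
#' @export
read_adduct_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ad in lines) parse_adduct(ad)   # validate; errors name the offender
  lines
}
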