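#' Previously validated M. smegmatis rRNA capture probes
#'
#' The nine published organism-specific capture probes for *Mycobacterium
#' smegmatis* str. MC2 155 (five against 16S rRNA, four against 23S rRNA),
#' each a 100-nt window of an rRNA gene with zero qualifying similarity
#' hits against the organism's coding sequences. Shipped as a reference
#' set for validating the screening machinery and as example probe input.
#'
#' @return Tibble with columns `id` (`16S-1` .. `23S-4`) and `sequence`.
#' @examples
#' msmeg_probes()
#' @export
msmeg_probes <- function() {
  read_fasta(system.file("extdata", "msmeg_rrna_probes.fasta",
                         package = "riboprobe", mustWork = TRUE))
}
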