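# Re-export the tidy generics the package provides methods for, so users
# get the grammar without attaching dplyr/tidyr themselves.

#' @importFrom dplyr mutate
#' @export
dplyr::mutate

#' @importFrom dplyr rename
#' @export
dplyr::rename

#' @importFrom dplyr select
#' @export
dplyr::select

#' @importFrom dplyr filter
#' @export
dplyr::filter

#' @importFrom dplyr slice
#' @export
dplyr::slice

#' @importFrom dplyr arrange
#' @export
dplyr::arrange

#' @importFrom dplyr group_by
#' @export
dplyr::group_by

#' @importFrom dplyr ungroup
#' @export
dplyr::ungroup

#' @importFrom dplyr group_vars
#' @export
dplyr::group_vars

#' @importFrom dplyr count
#' @export
dplyr::count

#' @importFrom dplyr add_count
#' @export
dplyr::add_count

#' @importFrom dplyr summarise
#' @export
dplyr::summarise

#' @importFrom dplyr summarize
#' @export
dplyr::summarize

#' @importFrom dplyr distinct
#' @export
dplyr::distinct

#' @importFrom dplyr pull
#' @export
dplyr::pull

#' @importFrom tidyr separate
#' @export
tidyr::separate

#' @importFrom tidyr unite
#' @export
tidyr::unite

#' @importFrom tidyr extract
#' @export
tidyr::extract

#' @importFrom tidyr pivot_longer
#' @export
tidyr::pivot_longer
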