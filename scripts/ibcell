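#!/usr/bin/env Rscript
# Thin command-line wrapper over the installed ibcell package:
#   ibcell run      --config FILE --out DIR
#   ibcell sweep    --config FILE --grid "G=15,25;D=10,65;E=12.5" --out chart.csv
#   ibcell tune     --config FILE --targets targets.csv --out path.json
#   ibcell quantify --snapshots DIR --out counts.csv
#   ibcell render   --snapshot FILE --out img.pdf
#   ibcell fixtures --name NAME
suppressPackageStartupMessages(library(ibcell))
status <- tryCatch(ibcell_cli(commandArgs(trailingOnly = TRUE)),
                   error = function(e) {
                     message("ibcell: ", conditionMessage(e))
                     1L
                   })
quit(status = if (is.null(status)) 0L else as.integer(status))
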