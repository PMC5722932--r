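#!/usr/bin/env Rscript
# Run every packaged fixture through the pipeline and assert the headline
# results; exits non-zero if any check fails. See reproduce_paper().

library(camps)
report <- reproduce_paper()
print(report)
if (!report$all_pass) quit(status = 1)
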