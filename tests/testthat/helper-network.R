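# the network build (decoder-weight solve) is the expensive step; share
# one instance across test files
.test_net_env <- new.env()

test_network <- function() {
  if (is.null(.test_net_env$net))
    .test_net_env$net <- build_network()
  .test_net_env$net
}
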