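#ifndef GWASMPC_SHA256_H
#define GWASMPC_SHA256_H

#include <cstdint>
#include <cstddef>

// Minimal SHA-256 (FIPS 180-4).  Used as the PRF for garbled-table key
// derivation and as the extractor/keystream for the OT group elements.
struct Sha256Ctx {
  uint32_t state[8];
  uint64_t bitlen;
  uint8_t buffer[64];
  size_t buflen;
};

void sha256_init(Sha256Ctx *ctx);
void sha256_update(Sha256Ctx *ctx, const uint8_t *data, size_t len);
void sha256_final(Sha256Ctx *ctx, uint8_t out[32]);
void sha256(const uint8_t *data, size_t len, uint8_t out[32]);

#endif
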