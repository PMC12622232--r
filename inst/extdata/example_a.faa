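>p1
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
>p2
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
>p3
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
>p4
MKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDNPILFWYHCAKGVTMESMKVLATQERSGDN
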